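# shared fixture builders; everything is generated in code

random_feature_matrix <- function(nf = 6, ns = 4, missing = 0.2, seed = 1,
                                  is_log = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(nf * ns, 20, 2), nf, ns,
              dimnames = list(sprintf("F%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  if (missing > 0) x[runif(nf * ns) < missing] <- NA
  feature_matrix(x, is_log = is_log)
}

# M1 -> E1 -> M2 -> E2 -> ... linear chain as a reaction_network
chain_network <- function(n_met) {
  simulate_network_truth(n_met, 1)$network
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# vectorised net-charge oracle, written independently of the package's
# group-census implementation: counts residues directly
oracle_charge <- function(sequence, ph) {
  letters <- strsplit(sequence, "")[[1]]
  pka <- c(Nterm = 9.094, Cterm = 2.869, D = 3.872, E = 4.412, C = 7.555,
           Y = 10.85, H = 5.637, K = 9.052, R = 11.84)
  pos <- 1 / (1 + 10^(ph - pka["Nterm"])) +
    sum(letters == "H") / (1 + 10^(ph - pka["H"])) +
    sum(letters == "K") / (1 + 10^(ph - pka["K"])) +
    sum(letters == "R") / (1 + 10^(ph - pka["R"]))
  neg <- 1 / (1 + 10^(pka["Cterm"] - ph)) +
    sum(letters == "D") / (1 + 10^(pka["D"] - ph)) +
    sum(letters == "E") / (1 + 10^(pka["E"] - ph)) +
    sum(letters == "C") / (1 + 10^(pka["C"] - ph)) +
    sum(letters == "Y") / (1 + 10^(pka["Y"] - ph))
  unname(pos - neg)
}

# grid-search pI oracle on a 0.001-pH grid
oracle_pi <- function(sequence, step = 0.001) {
  grid <- seq(0, 14, by = step)
  grid[which.min(abs(oracle_charge(sequence, grid)))]
}

# subset a cohort's protein matrix to one method's tissue samples
method_subset <- function(m, annotation, method) {
  keep <- annotation$sample_id[annotation$method == method &
                                 !grepl("_met$", annotation$sample_id)]
  m$values <- m$values[, intersect(colnames(m$values), keep), drop = FALSE]
  m
}
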