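# small in-code fixtures shared across test files

make_geno <- function(dosages, ids = NULL, markers = NULL) {
  m <- as.matrix(dosages)
  storage.mode(m) <- "double"
  rownames(m) <- ids %||% paste0("A", seq_len(nrow(m)))
  colnames(m) <- markers %||% paste0("M", seq_len(ncol(m)))
  geno_matrix(m)
}

write_geno_file <- function(dosages, path = tempfile(fileext = ".csv"),
                            sep = ",") {
  m <- as.matrix(dosages)
  ids <- paste0("A", seq_len(nrow(m)))
  markers <- paste0("M", seq_len(ncol(m)))
  lines <- c(paste(c("id", markers), collapse = sep),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(ids[i], m[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  path
}

# tiny regression instance with a centered design, used by sampler tests
make_regression <- function(n = 30, q = 5, seed = 99, mu = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * q), n, q,
              dimnames = list(paste0("A", seq_len(n)), paste0("M", seq_len(q))))
  X <- scale(X, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  beta <- c(1, -0.5, rep(0, q - 2))
  y <- drop(X %*% beta) + rnorm(n) + mu
  g <- geno_matrix(X, allele_freq = rep(0.5, q), centered = TRUE,
                   centers = rep(1, q))
  list(g = g, phen = tibble::tibble(id = rownames(X), value = y),
       X = X, y = y, beta = beta)
}

# batch-means Monte-Carlo standard error (accounts for autocorrelation)
mc_se <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- n %/% n_batches
  bm <- colMeans(matrix(x[seq_len(bs * n_batches)], nrow = bs))
  sd(bm) / sqrt(n_batches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
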