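options(microsync.quiet = TRUE)

# Small hand-built uptake table: 4 subjects x 3 VOIs, strictly positive.
tiny_table <- function() {
  vals <- matrix(c(1.0, 2.0, 3.0,
                   1.5, 2.5, 3.5,
                   0.8, 1.6, 2.4,
                   1.2, 2.2, 3.1),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  uptake_table(vals)
}

tiny_atlas <- function() {
  atlas_metadata(c("A", "B", "C"),
                 c("cortical", "cortical", "subcortical"),
                 "bilateral")
}

# Random positive uptake table for property loops.
random_table <- function(n, p, seed) {
  vals <- with_fixed_seed(seed, matrix(5 + rnorm(n * p), n, p))
  dimnames(vals) <- list(sprintf("s%02d", seq_len(n)),
                         sprintf("v%02d", seq_len(p)))
  uptake_table(vals)
}

# Fresh scratch file path in the session temp dir (cleaned by R on exit).
scratch_file <- function(name) {
  file.path(tempdir(), paste0(sample.int(1e9, 1), "_", name))
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Hand-assembled symmetric ICC object for threshold/summary tests.
manual_icc <- function(vois, z_vals, p_vals, n_subjects = 10) {
  p <- length(vois)
  z <- matrix(NA_real_, p, p, dimnames = list(vois, vois))
  pv <- z
  k <- 1
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      z[i, j] <- z[j, i] <- z_vals[k]
      pv[i, j] <- pv[j, i] <- p_vals[k]
      k <- k + 1
    }
  }
  structure(list(vois = vois, z_mean = z, p_values = pv,
                 n_subjects = n_subjects, n_rep = 1L, seed = NA_integer_,
                 n_invalid = matrix(0L, p, p)),
            class = "icc_matrix")
}
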