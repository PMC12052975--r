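# Independent oracles used across the suite. Each one re-derives the target
# quantity by the most literal route available (enumeration, direct
# arithmetic, finite differences) without touching the implementation path
# it checks.

kB_ref <- 0.0083144621

# exhaustive enumeration of global alignments under affine gap costs
# (a gap run of length L costs open + L * ext); exponential, short pairs only
brute_align_score <- function(a, b, S, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, state, sc) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1L, j + 1L, 0L, sc + S[A[i], B[j]])
    if (i <= length(A))
      rec(i + 1L, j, 1L, sc + ext + if (state != 1L) open else 0)
    if (j <= length(B))
      rec(i, j + 1L, 2L, sc + ext + if (state != 2L) open else 0)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# nested grid search over (intercept, beta1, beta2) for the ridge logistic
# objective: mean cross-entropy + lambda/2 * ||beta||^2
grid_logistic_oracle <- function(X, y, lambda, half = 4, levels = 6) {
  obj <- function(th) {
    eta <- th[1] + X %*% th[-1]
    mean(log1p(exp(eta)) - y * eta) + lambda / 2 * sum(th[-1]^2)
  }
  center <- c(0, 0, 0)
  for (lv in seq_len(levels)) {
    g <- seq(-half, half, length.out = 17)
    pts <- as.matrix(expand.grid(center[1] + g, center[2] + g, center[3] + g))
    vals <- apply(pts, 1, obj)
    center <- unname(pts[which.min(vals), ])
    half <- half * 2 / 16 # shrink to twice the current grid spacing
  }
  center
}

# direct finite-difference force check
fd_force <- function(f, z, h = 1e-6) -(f(z + h) - f(z - h)) / (2 * h)

# small random aligned panels for position-mapping round trips
random_alignment <- function(n_rows, ref_len, gap_p = 0.3, seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- sample(aa, ref_len, replace = TRUE)
  ncol_total <- ref_len + rbinom(1, ref_len, gap_p)
  ref_cols <- sort(sample(ncol_total, ref_len))
  ref_row <- rep("-", ncol_total)
  ref_row[ref_cols] <- ref
  rows <- replicate(n_rows, {
    r <- sample(aa, ncol_total, replace = TRUE)
    r[sample(ncol_total, rbinom(1, ncol_total, gap_p))] <- "-"
    paste(r, collapse = "")
  })
  data.frame(id = c("REF", paste0("s", seq_len(n_rows))),
             taxon = "unknown",
             residues = c(paste(ref_row, collapse = ""), rows),
             stringsAsFactors = FALSE)
}
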