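#' Assemble a design matrix from contact-frequency tables
#'
#' One row per simulation (molecule, variant, replicate), one column per
#' residue (the union across tables, sorted by residue number then label;
#' residues absent from a table are filled with 0). Values are adjusted
#' contact frequencies. With `standardize = TRUE` each column is z-scored
#' (mean 0, sd 1; constant columns are left at 0) and the centring/scaling
#' parameters are stored for reporting on the original scale.
#'
#' @param tables list of [contact_frequency_table()]s, each with metadata
#'   fields `molecule` and `variant` (and optionally `replicate`).
#' @param labels data.frame with columns `molecule`, `variant`,
#'   `transported` (0/1) covering every table.
#' @param standardize z-score the columns (default TRUE).
#' @return list with `X` (numeric matrix; attributes `center`, `scale`,
#'   `standardized`, `row_info`) and `y` (0/1 integer vector).
#' @export
build_design_matrix <- function(tables, labels, standardize = TRUE) {
  stopifnot(is.list(tables), length(tables) >= 2,
            all(c("molecule", "variant", "transported") %in% names(labels)))
  info <- do.call(rbind, lapply(seq_along(tables), function(i) {
    m <- attr(tables[[i]], "metadata")
    data.frame(molecule = as.character(m$molecule %||% NA),
               variant = as.character(m$variant %||% NA),
               replicate = as.character(m$replicate %||% i),
               stringsAsFactors = FALSE)
  }))
  key <- paste(info$molecule, info$variant)
  lkey <- paste(labels$molecule, labels$variant)
  miss <- !key %in% lkey
  if (any(miss))
    stop("unlabeled simulations: ", paste(unique(key[miss]), collapse = ", "))
  y <- as.integer(labels$transported[match(key, lkey)])

  residues <- sort_residues(unique(unlist(lapply(tables, `[[`, "residue"))))
  X <- matrix(0, nrow = length(tables), ncol = length(residues),
              dimnames = list(NULL, residues))
  for (i in seq_along(tables)) {
    t_i <- tables[[i]]
    X[i, match(t_i$residue, residues)] <- t_i$adjusted_frequency
  }
  stopifnot(!anyNA(X))
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize) {
    ctr <- colMeans(X)
    # population sd, so a two-row column (0.2, 0.4) maps to (-1, +1)
    scl <- sqrt(colMeans(sweep(X, 2, ctr, "-")^2))
    const <- scl < 1e-12
    Xs <- sweep(X, 2, ctr, "-")
    Xs <- sweep(Xs, 2, ifelse(const, 1, scl), "/")
    Xs[, const] <- 0
    X <- Xs
  }
  attr(X, "center") <- setNames(ctr, residues)
  attr(X, "scale") <- setNames(scl, residues)
  attr(X, "standardized") <- standardize
  attr(X, "row_info") <- info
  list(X = X, y = y)
}

sort_residues <- function(labels) {
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", labels)))
  num[is.na(num)] <- .Machine$integer.max
  labels[order(num, labels)]
}

#' Fit an L2-regularised logistic model of transport
#'
#' Minimises mean binomial cross-entropy plus `lambda/2 * ||beta||^2` (the
#' intercept is not penalised) by damped Newton iterations from a zero
#' start. The objective is non-increasing across accepted iterations;
#' convergence is declared when the gradient norm falls below `tol`.
#' Refitting identical inputs reproduces coefficients exactly.
#'
#' @param X numeric design matrix (rows = simulations, cols = residues),
#'   as from [build_design_matrix()].
#' @param y 0/1 labels (both classes must be present).
#' @param lambda ridge strength >= 0 (default 1).
#' @param max_iter Newton iteration cap (default 100).
#' @param tol gradient-norm tolerance (default 1e-8).
#' @return object of class `abcg_logit`: `beta` (named), `intercept`,
#'   `lambda`, `convergence` (iterations, final gradient norm, converged
#'   flag), `standardization` (center/scale if X carried them).
#' @export
fit_logistic <- function(X, y, lambda = 1.0, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)), lambda >= 0)
  if (length(unique(y)) < 2L)
    stop("both transport classes must be present to fit")
  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p); b0 <- 0

  obj <- function(b0, beta) {
    eta <- b0 + drop(X %*% beta)
    # log(1 + exp(.)) stably
    ll <- mean(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta)
    ll + lambda / 2 * sum(beta^2)
  }
  J <- obj(b0, beta)
  it <- 0L; gnorm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    eta <- b0 + drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g0 <- mean(mu - y)
    gb <- drop(crossprod(X, mu - y)) / n + lambda * beta
    gnorm <- sqrt(g0^2 + sum(gb^2))
    if (gnorm < tol) break
    H <- matrix(0, p + 1L, p + 1L)
    H[1, 1] <- mean(w)
    H[1, -1] <- H[-1, 1] <- drop(crossprod(X, w)) / n
    H[-1, -1] <- crossprod(X * w, X) / n + diag(lambda, p)
    step <- solve(H, c(g0, gb))
    t_sz <- 1
    repeat {
      b0_new <- b0 - t_sz * step[1]
      beta_new <- beta - t_sz * step[-1]
      J_new <- obj(b0_new, beta_new)
      if (J_new <= J + 1e-12 || t_sz < 1e-8) break
      t_sz <- t_sz / 2
    }
    b0 <- b0_new; beta <- beta_new; J <- J_new
  }
  converged <- gnorm < tol
  if (!converged)
    warning("logistic fit did not converge in ", max_iter,
            " iterations (gradient norm ", signif(gnorm, 3), ")")
  if (lambda == 0 && max(abs(beta)) > 50)
    warning("lambda = 0 on (near-)separable data: coefficients bounded ",
            "only by the iteration cap")
  structure(list(beta = setNames(beta, colnames(X)), intercept = b0,
                 lambda = lambda,
                 convergence = list(iterations = it,
                                    gradient_norm = gnorm,
                                    converged = converged),
                 standardization = list(center = attr(X, "center"),
                                        scale = attr(X, "scale"),
                                        standardized = isTRUE(attr(X, "standardized")))),
            class = "abcg_logit")
}

#' @export
print.abcg_logit <- function(x, ...) {
  cat("<abcg_logit>", length(x$beta), "residues, lambda =", x$lambda,
      "| iterations:", x$convergence$iterations,
      "| converged:", x$convergence$converged, "\n")
  invisible(x)
}

#' Signed residue importance from a fitted model
#'
#' Residues with positive coefficients promote transport; negative
#' coefficients counteract it; coefficients within 1e-10 of zero are
#' neutral. Rows are sorted by absolute coefficient (descending), ties
#' broken by residue number.
#'
#' @param model an `abcg_logit`.
#' @return data.frame with `residue`, `coefficient`, `class` in
#'   `{promote, counteract, neutral}`.
#' @export
residue_importance <- function(model) {
  stopifnot(inherits(model, "abcg_logit"))
  beta <- model$beta
  cls <- ifelse(abs(beta) < 1e-10, "neutral",
                ifelse(beta > 0, "promote", "counteract"))
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", names(beta))))
  num[is.na(num)] <- .Machine$integer.max
  ord <- order(-abs(beta), num, names(beta))
  data.frame(residue = names(beta)[ord], coefficient = unname(beta[ord]),
             class = unname(cls[ord]), stringsAsFactors = FALSE)
}

#' Electronic pocket-ligand binding energy
#'
#' `E_el = E_PL - (E_P + E_L)`: the electronic interaction energy of the
#' pocket-ligand complex relative to its isolated parts (all in the same
#' units, conventionally kcal/mol). Negative values indicate favourable
#' binding; a positive value rules the ligand out as a transport-competent
#' binder.
#'
#' @param e_pl complex energy.
#' @param e_p pocket energy.
#' @param e_l ligand energy.
#' @return the interaction energy, with attribute `classification` in
#'   `{binder, non-binder, undetermined}`.
#' @examples
#' electronic_binding_energy(-100, -60, -20) # -20, binder
#' @export
electronic_binding_energy <- function(e_pl, e_p, e_l) {
  stopifnot(is.finite(e_pl), is.finite(e_p), is.finite(e_l))
  e <- e_pl - (e_p + e_l)
  attr(e, "classification") <-
    if (e < 0) "binder" else if (e > 0) "non-binder" else "undetermined"
  e
}
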