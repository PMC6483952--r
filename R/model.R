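#' Model variant switchboard
#'
#' Maps a variant number 1-4 to its design-matrix kind and variance
#' partition scheme: 1 = (probability, equal), 2 = (indicator, equal),
#' 3 = (probability, size-weighted), 4 = (indicator, size-weighted).
#'
#' @param variant Integer in 1..4.
#' @return List with `variant_number`, `z_kind`, `variance_scheme`.
#' @export
model_variant <- function(variant) {
  variant <- as.integer(variant)
  if (!variant %in% 1:4) stop("variant must be 1, 2, 3 or 4")
  list(variant_number = variant,
       z_kind = if (variant %in% c(1, 3)) "probability" else "indicator",
       variance_scheme = if (variant %in% c(1, 2)) "equal" else "size_weighted")
}

#' Build the haplotype design matrix
#'
#' One column per selected haplotype allele. The probability kind holds
#' the probability that the animal transmits the haplotype — its expected
#' number of copies under the diplotype posterior divided by 2, in
#' `[0, 1]` (an expected-dosage scale in `[0, 2]` is available via
#' `scale = "dosage"`). The indicator kind holds 1 when the animal's most
#' probable diplotype at the block contains the allele, else 0. Animals
#' with no posterior for a block fall back to the population prior: the
#' allele frequency for the probability kind, the modal Hardy-Weinberg
#' diplotype for the indicator kind.
#'
#' @param posteriors Posterior table from [phase_blocks()] (columns
#'   `animal_id`, `block_id`, `a`, `b`, `probability`).
#' @param selected Selected-haplotype table (columns `block_id`,
#'   `allele_index`, `allele_string`, `population_frequency`); column
#'   order of the result follows its row order.
#' @param animal_ids Animals to build rows for.
#' @param z_kind `"probability"` or `"indicator"`.
#' @param scale For the probability kind: `"transmission"` (expected
#'   copies / 2, default) or `"dosage"` (expected copies).
#' @return Numeric matrix with `animal_ids` as rownames and haplotype keys
#'   `"b<block>:<allele string>"` as colnames.
#' @export
build_design_matrix <- function(posteriors, selected, animal_ids,
                                z_kind = c("probability", "indicator"),
                                scale = c("transmission", "dosage")) {
  z_kind <- match.arg(z_kind)
  scale <- match.arg(scale)
  H <- nrow(selected)
  if (H < 1) stop("no selected haplotypes")
  Z <- matrix(0, length(animal_ids), H,
              dimnames = list(animal_ids,
                              paste0("b", selected$block_id, ":",
                                     selected$allele_string)))
  div <- if (scale == "transmission") 2 else 1
  for (b in unique(selected$block_id)) {
    sel_b <- selected[selected$block_id == b, , drop = FALSE]
    post_b <- posteriors[posteriors$block_id == b, , drop = FALSE]
    covered <- intersect(animal_ids, post_b$animal_id)
    absent <- setdiff(animal_ids, covered)
    cols <- match(paste0("b", sel_b$block_id, ":", sel_b$allele_string),
                  colnames(Z))
    if (z_kind == "probability") {
      for (s in seq_len(nrow(sel_b))) {
        j <- sel_b$allele_index[s]
        copies <- (post_b$a == j) + (post_b$b == j)
        dos <- tapply(post_b$probability * copies, post_b$animal_id, sum)
        dos <- dos[covered]
        Z[covered, cols[s]] <- unname(dos) / div
        if (length(absent)) {
          Z[absent, cols[s]] <- 2 * sel_b$population_frequency[s] / div
        }
      }
    } else {
      # modal diplotype per animal; deterministic tie-break by descending
      # probability, then allele indices
      ord <- order(post_b$animal_id, -post_b$probability, post_b$a, post_b$b)
      post_b <- post_b[ord, , drop = FALSE]
      modal <- post_b[!duplicated(post_b$animal_id), , drop = FALSE]
      modal <- modal[match(covered, modal$animal_id), , drop = FALSE]
      for (s in seq_len(nrow(sel_b))) {
        j <- sel_b$allele_index[s]
        Z[covered, cols[s]] <- as.numeric(modal$a == j | modal$b == j)
      }
      if (length(absent)) {
        warning("block ", b, ": ", length(absent),
                " animal(s) without posterior; using prior modal diplotype")
        # modal HW pair over the block's full frequency table is not
        # available from `selected` alone; approximate with the selected
        # alleles' frequencies plus an implicit "other" allele mass
        freq <- sel_b$population_frequency
        other <- max(0, 1 - sum(freq))
        fr <- c(freq, other)
        jj <- c(sel_b$allele_index, NA)
        best <- c(NA, NA)
        best_p <- -1
        for (x in seq_along(fr)) for (y in x:length(fr)) {
          p <- if (x == y) fr[x]^2 else 2 * fr[x] * fr[y]
          if (p > best_p) {
            best_p <- p
            best <- c(jj[x], jj[y])
          }
        }
        for (s in seq_len(nrow(sel_b))) {
          j <- sel_b$allele_index[s]
          Z[absent, cols[s]] <- as.numeric(j %in% best[!is.na(best)])
        }
      }
    }
    if (length(absent) && z_kind == "probability") {
      warning("block ", b, ": ", length(absent),
              " animal(s) without posterior; using population prior")
    }
  }
  attr(Z, "z_kind") <- z_kind
  Z
}

#' Partition the genetic variance across haplotypes
#'
#' Equal scheme: every selected haplotype receives `sigma2_g / H`.
#' Size-weighted scheme: haplotype j receives
#' `sigma2_g * L_j / sum(L)`, where `L_j` is the SNP count of its block,
#' so longer haplotypes carry more of the variance. Both schemes sum to
#' `sigma2_g` exactly (the last element absorbs the floating-point
#' residual).
#'
#' @param selected Selected-haplotype table with a `block_size` column.
#' @param genetic_variance sigma2_g, positive.
#' @param scheme `"equal"` or `"size_weighted"`.
#' @return Named numeric vector of per-haplotype variances.
#' @export
partition_variance <- function(selected, genetic_variance,
                               scheme = c("equal", "size_weighted")) {
  scheme <- match.arg(scheme)
  H <- nrow(selected)
  if (H < 1) stop("no selected haplotypes")
  if (genetic_variance <= 0) stop("genetic_variance must be positive")
  v <- if (scheme == "equal") {
    rep(genetic_variance / H, H)
  } else {
    L <- selected$block_size
    genetic_variance * (L / sum(L))
  }
  if (H > 1) {
    # make the sum land on genetic_variance exactly: measure the exact
    # residual of the floating-point sum (Neumaier compensation) and
    # absorb it into the smallest element, whose finer ulp places the
    # corrected sum strictly inside genetic_variance's rounding interval
    for (it in 1:5) {
      if (sum(v) == genetic_variance) break
      s <- 0
      comp <- 0
      for (xi in v) {
        t <- s + xi
        comp <- comp + if (abs(s) >= abs(xi)) (s - t) + xi else (xi - t) + s
        s <- t
      }
      j <- which.min(v)
      v[j] <- v[j] - ((s - genetic_variance) + comp)
    }
  }
  names(v) <- paste0("b", selected$block_id, ":", selected$allele_string)
  v
}

#' Solve the random-haplotype-effect linear model
#'
#' Fits `y = mu + Z h + e` with `h_j ~ N(0, sigma2_h_j)` and
#' `e_i ~ N(0, sigma2_e / w_i)` by building and solving the mixed model
#' equations
#' \deqn{\left[\begin{array}{cc} 1'R^{-1}1 & 1'R^{-1}Z \\ Z'R^{-1}1 &
#'   Z'R^{-1}Z + G^{-1}\end{array}\right]
#'   \left[\begin{array}{c}\hat\mu\\ \hat h\end{array}\right] =
#'   \left[\begin{array}{c}1'R^{-1}y\\ Z'R^{-1}y\end{array}\right]}
#' with `G = diag(sigma2_h)` and `R = diag(sigma2_e / w)`. The symmetric
#' system is solved by Cholesky factorisation; if it is singular (possible
#' only in degenerate limits) the minimum-norm solution is returned with
#' a warning naming any all-zero design columns. `mu` is a fixed effect
#' (BLUE); `h` are random (BLUP).
#'
#' @param y Numeric response vector (deregressed proofs).
#' @param Z Design matrix from [build_design_matrix()], rows matching `y`.
#' @param sigma2_h Per-haplotype variances (length `ncol(Z)`, positive).
#' @param sigma2_e Residual variance (positive).
#' @param weights Optional positive per-animal weights `w_i` (residual
#'   variance `sigma2_e / w_i`); default all 1.
#' @return A list of class `haplotype_fit`: `mu_hat`, `effects` (named),
#'   `haplotype_variances`, `error_variance`, `fitted`, `residuals`.
#' @export
solve_model <- function(y, Z, sigma2_h, sigma2_e, weights = NULL) {
  n <- length(y)
  if (nrow(Z) != n) stop("rows of Z must match length of y")
  H <- ncol(Z)
  if (length(sigma2_h) != H) stop("need one variance per haplotype column")
  if (any(sigma2_h <= 0)) stop("haplotype variances must be positive")
  if (sigma2_e <= 0) stop("error_variance must be positive")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (any(w <= 0) || any(!is.finite(w))) stop("weights must be positive and finite")
  rinv <- w / sigma2_e
  ZtR <- Z * rinv
  C <- rbind(
    c(sum(rinv), colSums(ZtR)),
    cbind(colSums(ZtR), crossprod(Z, ZtR) + diag(1 / sigma2_h, H)))
  rhs <- c(sum(rinv * y), crossprod(Z, rinv * y))
  sol <- tryCatch(
    drop(chol2inv(chol(C)) %*% rhs),
    error = function(e) {
      zero_cols <- colnames(Z)[colSums(Z != 0) == 0]
      warning("singular mixed model equations",
              if (length(zero_cols)) paste0(" (all-zero columns: ",
                                            paste(zero_cols, collapse = ", "),
                                            ")"),
              "; returning the minimum-norm solution")
      drop(MASS::ginv(C) %*% rhs)
    })
  mu <- sol[1]
  h <- sol[-1]
  names(h) <- colnames(Z)
  fitted <- mu + drop(Z %*% h)
  structure(list(mu_hat = mu, effects = h,
                 haplotype_variances = stats::setNames(sigma2_h, colnames(Z)),
                 error_variance = sigma2_e,
                 fitted = fitted, residuals = y - fitted),
            class = "haplotype_fit")
}

#' @export
print.haplotype_fit <- function(x, ...) {
  cat("haplotype_fit:", length(x$effects), "haplotype effects; mu =",
      signif(x$mu_hat, 6), "\n")
  invisible(x)
}

#' Predict direct genomic values
#'
#' `DGV_i = sum_j Z_ij h_j` — haplotype effects only, excluding the
#' overall mean.
#'
#' @param Z_new Design matrix whose columns match `fit$effects` exactly
#'   (same names, same order).
#' @param fit A `haplotype_fit` from [solve_model()].
#' @return data.frame with columns `animal_id`, `dgv`.
#' @export
predict_dgv <- function(Z_new, fit) {
  if (!identical(colnames(Z_new), names(fit$effects))) {
    stop("columns of Z_new do not match the fitted haplotype effects")
  }
  data.frame(animal_id = rownames(Z_new),
             dgv = drop(Z_new %*% fit$effects),
             stringsAsFactors = FALSE)
}
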