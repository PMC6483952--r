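# Enumerate the ordered haplotype pairs compatible with one genotype
# pattern (vector over {0,1,2,NA} of length L). Haplotypes are encoded as
# integers with bit s (1-based) = allele at SNP s. Returns a 2-column
# matrix of ordered pairs; heterozygous sites double the set, missing
# sites quadruple it.
.compatible_pairs <- function(pattern, pair_cap = 2^16) {
  a <- 0L
  b <- 0L
  pairs <- matrix(c(0L, 0L), 1, 2)
  for (s in seq_along(pattern)) {
    bit <- bitwShiftL(1L, s - 1L)
    call <- pattern[s]
    if (is.na(call)) {
      pairs <- rbind(pairs,
                     cbind(pairs[, 1] + bit, pairs[, 2]),
                     cbind(pairs[, 1], pairs[, 2] + bit),
                     cbind(pairs[, 1] + bit, pairs[, 2] + bit))
    } else if (call == 1L) {
      pairs <- rbind(cbind(pairs[, 1] + bit, pairs[, 2]),
                     cbind(pairs[, 1], pairs[, 2] + bit))
    } else if (call == 2L) {
      pairs <- pairs + bit
    }
    if (nrow(pairs) > pair_cap) return(NULL)
  }
  pairs
}

.hap_to_string <- function(code, L) {
  vapply(code, function(x)
    paste(as.integer(intToBits(x)[1:L]), collapse = ""), character(1))
}

#' Phase one haplotype block by multi-locus EM
#'
#' Estimates haplotype allele frequencies and per-animal diplotype
#' posteriors for a block of SNPs from unphased genotypes. The E-step
#' weights each animal's compatible unordered haplotype pairs `(j, k)` in
#' proportion to `f_j f_k` (`2 f_j f_k` for `j != k`); the M-step
#' re-estimates frequencies from the expected haplotype counts; iteration
#' stops when the log-likelihood improves by less than `tol` or after
#' `max_iter` sweeps. Missing calls are marginalised by enumerating every
#' compatible allele. The log-likelihood is checked to be non-decreasing
#' at every iteration. Alleles whose final frequency falls below machine
#' level (1e-12) are pruned and the posteriors renormalised.
#'
#' Animals with every call missing in the block (or with too many
#' ambiguous sites to enumerate) take the Hardy-Weinberg population prior
#' as their posterior and do not contribute to the likelihood.
#'
#' @param calls Matrix of genotype calls (animals x SNPs of one block),
#'   values in `{0, 1, 2, NA}`; at least 2 SNPs.
#' @param max_iter Maximum EM sweeps.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param enum_cap Maximum number of candidate haplotypes (`2^L`); blocks
#'   beyond the cap are refused with an error.
#' @param animal_ids Optional identifiers for the rows of `calls`.
#' @return A list of class `block_phase`: `alleles` (data.frame:
#'   `allele_index`, `allele_string`, `population_frequency`),
#'   `posteriors` (data.frame: `animal`, `animal_id`, `a`, `b` (allele
#'   indices, `a <= b`), `probability`), `loglik` (per-iteration trace),
#'   `n_iter`, `converged`.
#' @export
em_phase_block <- function(calls, max_iter = 500, tol = 1e-8,
                           enum_cap = 2^20, animal_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  n <- nrow(calls)
  if (L < 2) stop("a block needs at least 2 SNPs")
  if (n < 1 || all(is.na(calls))) {
    stop("need at least one animal with a non-missing call")
  }
  if (2^L > enum_cap) {
    stop("block enumeration exceeds cap: 2^", L, " > ", enum_cap,
         " candidate haplotypes")
  }
  if (is.null(animal_ids)) animal_ids <- as.character(seq_len(n))

  keys <- apply(calls, 1, function(r) paste(ifelse(is.na(r), "m", r),
                                            collapse = ""))
  upat <- !duplicated(keys)
  pat_of_animal <- match(keys, keys[upat])
  pat_rows <- which(upat)
  n_pat <- length(pat_rows)

  pat_pairs <- vector("list", n_pat)    # unordered pairs + multiplicity
  informative <- logical(n_pat)
  for (p in seq_len(n_pat)) {
    pattern <- calls[pat_rows[p], ]
    if (all(is.na(pattern))) next
    op <- .compatible_pairs(pattern)
    if (is.null(op)) next               # too ambiguous: falls back to prior
    lo <- pmin(op[, 1], op[, 2])
    hi <- pmax(op[, 1], op[, 2])
    key <- paste(lo, hi)
    first <- !duplicated(key)
    pat_pairs[[p]] <- data.frame(h1 = lo[first], h2 = hi[first],
                                 mult = ifelse(lo[first] == hi[first], 1, 2))
    informative[p] <- TRUE
  }
  if (!any(informative)) stop("no animal could be enumerated in this block")

  pat_count <- tabulate(pat_of_animal, n_pat)
  flat <- do.call(rbind, lapply(which(informative), function(p)
    cbind(p = p, pat_pairs[[p]])))
  hap_codes <- sort(unique(c(flat$h1, flat$h2)))
  K <- length(hap_codes)
  i1 <- match(flat$h1, hap_codes)
  i2 <- match(flat$h2, hap_codes)
  pid <- flat$p
  mult <- flat$mult
  wpat <- pat_count[informative]
  pmap <- match(pid, which(informative))  # row of wpat for each pair row
  n_em <- sum(wpat)

  f <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lik_row <- mult * f[i1] * f[i2]
    lik_pat <- as.vector(rowsum(lik_row, pmap))
    ll <- sum(wpat * log(lik_pat))
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-8) {
      stop("EM log-likelihood decreased; this indicates a defect")
    }
    ll_trace <- c(ll_trace, ll)
    if (length(ll_trace) > 1 &&
        abs(ll - ll_trace[length(ll_trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
    w_row <- lik_row / lik_pat[pmap] * wpat[pmap]
    cnt <- as.vector(rowsum(c(w_row, w_row), c(i1, i2), reorder = FALSE))
    # rowsum with reorder=FALSE orders by first appearance; map back
    grp <- unique(c(i1, i2))
    cnt_full <- numeric(K)
    cnt_full[grp] <- cnt
    f <- cnt_full / (2 * n_em)
  }

  # posterior weights at the final frequencies
  lik_row <- mult * f[i1] * f[i2]
  lik_pat <- as.vector(rowsum(lik_row, pmap))
  post_row <- lik_row / lik_pat[pmap]

  # prune machine-level alleles
  keep <- f > 1e-12
  if (!all(keep)) {
    drop_rows <- !(keep[i1] & keep[i2])
    i1 <- i1[!drop_rows]
    i2 <- i2[!drop_rows]
    pmap <- pmap[!drop_rows]
    post_row <- post_row[!drop_rows]
    renorm <- as.vector(rowsum(post_row, pmap))
    post_row <- post_row / renorm[match(pmap, sort(unique(pmap)))]
    old <- which(keep)
    i1 <- match(i1, old)
    i2 <- match(i2, old)
    hap_codes <- hap_codes[keep]
    f <- f[keep] / sum(f[keep])
    K <- length(hap_codes)
  }

  alleles <- data.frame(allele_index = seq_len(K),
                        allele_string = .hap_to_string(hap_codes, L),
                        population_frequency = f)

  # expand pattern-level posteriors to animals
  inf_pats <- which(informative)
  post_list <- vector("list", n)
  prior_pairs <- NULL
  for (an in seq_len(n)) {
    p <- pat_of_animal[an]
    slot <- match(p, inf_pats)
    if (!is.na(slot)) {
      rows <- pmap == slot
      post_list[[an]] <- data.frame(animal = an, a = i1[rows], b = i2[rows],
                                    probability = post_row[rows])
    } else {
      if (is.null(prior_pairs)) {
        j <- rep(seq_len(K), times = seq(K, 1))
        k <- unlist(lapply(seq_len(K), function(x) seq(x, K)))
        pr <- ifelse(j == k, f[j]^2, 2 * f[j] * f[k])
        prior_pairs <- data.frame(a = j, b = k, probability = pr / sum(pr))
      }
      post_list[[an]] <- cbind(animal = an, prior_pairs)
    }
  }
  posteriors <- do.call(rbind, post_list)
  posteriors$animal_id <- animal_ids[posteriors$animal]
  posteriors <- posteriors[, c("animal", "animal_id", "a", "b", "probability")]
  rownames(posteriors) <- NULL

  structure(list(alleles = alleles, posteriors = posteriors,
                 loglik = ll_trace, n_iter = length(ll_trace),
                 converged = converged),
            class = "block_phase")
}

#' Carrier frequency of a haplotype allele
#'
#' Fraction of animals judged to carry at least one copy of the allele:
#' an animal counts as a carrier when its posterior probability of
#' carrying one or more copies exceeds 0.5.
#'
#' @param posteriors Posterior data.frame from [em_phase_block()] (columns
#'   `animal`, `a`, `b`, `probability`).
#' @param allele Allele index to score.
#' @param n_animals Number of animals the posteriors cover; defaults to
#'   the number of distinct animals present.
#' @return A single value in `[0, 1]`.
#' @export
carrier_frequency <- function(posteriors, allele, n_animals = NULL) {
  if (is.null(n_animals)) n_animals <- length(unique(posteriors$animal))
  hit <- posteriors$a == allele | posteriors$b == allele
  if (!any(hit)) return(0)
  p_carry <- tapply(posteriors$probability[hit], posteriors$animal[hit], sum)
  sum(p_carry > 0.5) / n_animals
}

#' Phase every block and tabulate its haplotypes
#'
#' Runs [em_phase_block()] on each LD block and assembles the combined
#' haplotype table (with population and carrier frequencies) and the
#' combined diplotype posterior table. Blocks whose enumeration exceeds
#' `enum_cap` are skipped with a warning.
#'
#' @param g A [genotype_matrix()] (the QC-passed panel the blocks index).
#' @param blocks An `ld_blocks` object, or a list of SNP index vectors.
#' @param max_iter,tol,enum_cap Passed to [em_phase_block()].
#' @return A list of class `phase_set`: `haplotypes` (data.frame:
#'   `block_id`, `chromosome`, `block_size`, `allele_index`,
#'   `allele_string`, `population_frequency`, `carrier_frequency`),
#'   `posteriors` (data.frame: `animal`, `animal_id`, `block_id`, `a`,
#'   `b`, `probability`), `skipped_blocks`.
#' @export
phase_blocks <- function(g, blocks, max_iter = 500, tol = 1e-8,
                         enum_cap = 2^20) {
  if (inherits(blocks, "ld_blocks")) {
    idx_list <- lapply(blocks$blocks, `[[`, "snp_indices")
  } else {
    idx_list <- blocks
  }
  n <- n_animals(g)
  hap_rows <- list()
  post_rows <- list()
  skipped <- integer(0)
  for (b in seq_along(idx_list)) {
    idx <- idx_list[[b]]
    res <- tryCatch(
      em_phase_block(g$calls[, idx, drop = FALSE], max_iter = max_iter,
                     tol = tol, enum_cap = enum_cap,
                     animal_ids = g$animal_ids),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("block ", b, " skipped: ", conditionMessage(res))
      skipped <- c(skipped, b)
      next
    }
    al <- res$alleles
    al$carrier_frequency <- vapply(al$allele_index, function(j)
      carrier_frequency(res$posteriors, j, n_animals = n), numeric(1))
    al <- cbind(block_id = b, chromosome = g$chromosome[idx[1]],
                block_size = length(idx), al)
    hap_rows[[length(hap_rows) + 1L]] <- al
    post_rows[[length(post_rows) + 1L]] <-
      cbind(res$posteriors[, c("animal", "animal_id")], block_id = b,
            res$posteriors[, c("a", "b", "probability")])
  }
  structure(list(haplotypes = do.call(rbind, hap_rows),
                 posteriors = do.call(rbind, post_rows),
                 skipped_blocks = skipped),
            class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat("phase_set:", length(unique(x$haplotypes$block_id)), "blocks,",
      nrow(x$haplotypes), "haplotype alleles\n")
  invisible(x)
}

#' Select high-frequency haplotypes
#'
#' Keeps haplotype alleles whose frequency is strictly greater than
#' `threshold` — by default the carrier frequency (fraction of individuals
#' carrying the allele), with chromosome-count population frequency as the
#' alternative basis. Rows are ordered by block, then descending
#' frequency, ties broken by allele string.
#'
#' @param haplotypes Haplotype table from [phase_blocks()].
#' @param threshold Frequency threshold in `[0, 1)`; strict inequality.
#' @param basis `"carrier"` (default) or `"population"`.
#' @return The selected subset of `haplotypes`, reordered.
#' @export
select_frequent_haplotypes <- function(haplotypes, threshold = 0.25,
                                       basis = c("carrier", "population")) {
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  basis <- match.arg(basis)
  freq <- if (basis == "carrier") haplotypes$carrier_frequency
          else haplotypes$population_frequency
  out <- haplotypes[freq > threshold, , drop = FALSE]
  freq <- freq[haplotypes[[if (basis == "carrier") "carrier_frequency"
                           else "population_frequency"]] > threshold]
  out <- out[order(out$block_id, -freq, out$allele_string), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write phased haplotype and posterior tables
#'
#' @param phase A `phase_set` from [phase_blocks()].
#' @param hap_path,post_path Output paths (tab-delimited with header).
#' @param selected Optional selected-haplotype table; adds a `selected`
#'   flag column to the haplotype output.
#' @return Invisibly, `c(hap_path, post_path)`.
#' @export
write_phase_tables <- function(phase, hap_path, post_path, selected = NULL) {
  haps <- phase$haplotypes
  if (!is.null(selected)) {
    key <- paste(haps$block_id, haps$allele_string)
    haps$selected <- key %in% paste(selected$block_id, selected$allele_string)
  }
  utils::write.table(haps, hap_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(phase$posteriors, post_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(hap_path, post_path))
}
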