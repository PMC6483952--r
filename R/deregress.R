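#' Somatic cell score transform
#'
#' Converts a somatic cell count (cells per mL) to the somatic cell
#' score, `SCS = log2(SCC / 100000) + 3`.
#'
#' @param scc Positive somatic cell count(s), cells per mL.
#' @return The somatic cell score(s).
#' @export
scs_transform <- function(scc) {
  if (any(!is.finite(scc)) || any(scc <= 0)) {
    stop("scc must be positive")
  }
  log2(scc / 100000) + 3
}

#' Trait parameter specification
#'
#' Heritability and genetic variance of a trait; the residual variance
#' used with deregressed proofs defaults to the quantitative-genetic
#' relation `sigma2_e = sigma2_g * (1 - h2) / h2`, and can be overridden.
#'
#' @param name Trait label.
#' @param heritability h2 in `(0, 1]`.
#' @param genetic_variance sigma2_g, positive, squared trait units.
#' @param error_variance Optional explicit sigma2_e.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name, heritability, genetic_variance,
                       error_variance = NULL) {
  if (heritability <= 0 || heritability > 1) {
    stop("heritability must lie in (0, 1]")
  }
  if (genetic_variance <= 0) stop("genetic_variance must be positive")
  if (is.null(error_variance)) {
    error_variance <- genetic_variance * (1 - heritability) / heritability
  }
  if (error_variance < 0) stop("error_variance must be nonnegative")
  structure(list(name = name, heritability = heritability,
                 genetic_variance = genetic_variance,
                 error_variance = error_variance),
            class = "trait_spec")
}

#' Built-in trait parameter table
#'
#' Returns the heritabilities and genetic variances of the ten dairy
#' traits the package's analysis scripts use (production: MY, FY, PY;
#' conformation: STA, OFL, USU; fertility: NRK, PRP, OMC; udder health:
#' SCS), shipped as plain text in `inst/extdata/trait_parameters.tsv`.
#'
#' @return data.frame with columns `trait`, `h2`, `sigma2_g`.
#' @export
trait_parameters <- function() {
  path <- system.file("extdata", "trait_parameters.tsv",
                      package = "haploblup", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Deregress estimated breeding values
#'
#' Removes the shrinkage of the genetic evaluation by scaling each proof's
#' deviation from the group mean by its reliability:
#' `drp_i = m + (ebv_i - m) / REL_i` with `m = mean(ebv)`. A weight
#' `w_i = REL_i / (1 - REL_i)` is attached for optional weighted fitting
#' (infinite at REL = 1). The rule is a transparent reliability-scaled
#' deviation; it expands deviations (`|drp - m| >= |ebv - m|`, equality
#' iff REL = 1) and is pluggable should a full mixed-model deregression
#' be substituted.
#'
#' @param records data.frame with columns `animal_id`, `ebv`,
#'   `reliability` (and typically `birth_year`).
#' @param mean_ebv Optional fixed centring mean; defaults to the mean EBV
#'   of `records`.
#' @return `records` with columns `drp` and `weight` appended.
#' @export
deregress <- function(records, mean_ebv = NULL) {
  rel <- records$reliability
  if (any(!is.finite(rel)) || any(rel <= 0) || any(rel > 1)) {
    stop("reliability must lie in (0, 1]")
  }
  m <- if (is.null(mean_ebv)) mean(records$ebv) else mean_ebv
  records$drp <- m + (records$ebv - m) / rel
  records$weight <- ifelse(rel < 1, rel / (1 - rel), Inf)
  records
}

#' Read or write the trait table
#'
#' Tab-delimited with header: `animal_id`, `birth_year`, `ebv`,
#' `reliability`, and `drp`/`weight` once deregressed.
#'
#' @param path File path.
#' @return For the reader, a data.frame; the writer returns `path`
#'   invisibly.
#' @export
read_trait_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(animal_id = "character"))
}

#' @rdname read_trait_table
#' @param records data.frame of proof records.
#' @export
write_trait_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
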