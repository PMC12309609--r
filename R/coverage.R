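#' Allele-frequency tables
#'
#' Per-population, per-locus allele frequencies used for coverage
#' calculations. Frequencies must be non-negative; they may sum to less
#' than 1 (untyped remainder), which is logged via a message on
#' construction when the shortfall exceeds the tolerance.
#'
#' @param frequencies named non-negative numeric vector (names = alleles).
#' @param population population name.
#' @param locus one of `"A"`, `"B"`, `"C"`, `"KIR3DL1"`.
#' @param tol tolerance on the sum exceeding 1.
#' @return an object of class `frequency_table`.
#' @export
frequency_table <- function(frequencies, population = "pop", locus = "A",
                            tol = 1e-6) {
  if (length(frequencies) == 0L) stopf("empty frequency table")
  if (is.null(names(frequencies)) || any(names(frequencies) == ""))
    stopf("frequencies must be named by allele")
  if (any(frequencies < 0)) stopf("frequencies must be non-negative")
  if (sum(frequencies) > 1 + tol)
    stopf("frequencies sum to %.4f > 1", sum(frequencies))
  structure(list(population = population, locus = locus,
                 entries = frequencies),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("frequency_table %s/%s: %d alleles, total frequency %.3f\n",
              x$population, x$locus, length(x$entries), sum(x$entries)))
  invisible(x)
}

#' Fraction of a population covered by tested alleles at one locus
#'
#' Sum of the frequencies of alleles present in the tested panel divided
#' by the total tabulated frequency (default), i.e. frequencies are
#' renormalized to sum 1 per locus. With `renormalize = FALSE` the untyped
#' remainder counts as uncovered (divide by 1).
#'
#' @param f a [frequency_table()].
#' @param tested character vector of tested allele names.
#' @param renormalize divide by the tabulated total (default `TRUE`).
#' @return fraction in `[0, 1]`.
#' @export
locus_coverage <- function(f, tested, renormalize = TRUE) {
  stopifnot(inherits(f, "frequency_table"))
  covered <- sum(f$entries[names(f$entries) %in% tested])
  covered / if (renormalize) sum(f$entries) else 1
}

#' Joint KIR x HLA coverage partition
#'
#' Under independence of KIR3DL1 and HLA coverage, splits the population
#' into the four fractions of the coverage diagram: both covered,
#' KIR-only, HLA-only, neither. The four parts always sum to 1.
#'
#' @param kir_cov,hla_cov coverage fractions in `[0, 1]`.
#' @return named numeric vector `both`, `kir_only`, `hla_only`, `neither`.
#' @export
joint_partition <- function(kir_cov, hla_cov) {
  if (kir_cov < 0 || kir_cov > 1 || hla_cov < 0 || hla_cov > 1)
    stopf("coverage fractions must lie in [0, 1]")
  c(both = kir_cov * hla_cov,
    kir_only = kir_cov * (1 - hla_cov),
    hla_only = (1 - kir_cov) * hla_cov,
    neither = (1 - kir_cov) * (1 - hla_cov))
}

#' Full-genotype coverage under independence
#'
#' Each individual carries two alleles at each of HLA-A, -B and -C; under
#' Hardy-Weinberg/independence the fraction of genotypes with *all six*
#' alleles covered is the product of the squared per-locus coverages.
#' An optional KIR3DL1 coverage factor multiplies in (squared) when the
#' receptor side should be included.
#'
#' @param cov_a,cov_b,cov_c per-locus coverage fractions in `[0, 1]`.
#' @param cov_kir optional KIR3DL1 coverage to include.
#' @return fraction in `[0, 1]`.
#' @export
genotype_coverage <- function(cov_a, cov_b, cov_c, cov_kir = NULL) {
  v <- c(cov_a, cov_b, cov_c, cov_kir)
  if (any(v < 0 | v > 1)) stopf("coverage fractions must lie in [0, 1]")
  prod(v^2)
}
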