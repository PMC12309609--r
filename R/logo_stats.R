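#' Two-sample logo enrichment between groups of aligned sequences
#'
#' For every (position, residue) pair observed in either group, tests
#' whether the residue's frequency differs between the groups with an exact
#' two-sided binomial test, and reports the frequency difference as the
#' effect (the letter height of a rendered logo is proportional to
#' `|effect|`). Significance is Bonferroni-controlled over all tested
#' pairs. Unknown (`*`) residues are excluded from the counts at their
#' position.
#'
#' Two null formulations are available. The default (`"pooled"`) is the
#' exact conditional two-sample binomial test: given the pooled count
#' `cA + cB` of a residue, `cA` is binomial with success probability
#' `nA / (nA + nB)` under the null of equal frequencies. It is exactly
#' symmetric in the two groups (swapping A and B negates effects and leaves
#' p-values unchanged) and exactly valid. The `"opposite"` variant tests
#' `cA` out of `nA` against group B's observed frequency as the null
#' proportion (and takes the smaller of the two directions' p-values).
#'
#' @param group_a,group_b [allele_panel()] objects or character vectors of
#'   aligned sequences.
#' @param alpha family-wise significance level (default 0.05).
#' @param null `"pooled"` (exact conditional, default) or `"opposite"`.
#' @return A data frame of class `logo_result` with columns `position`,
#'   `residue`, `freq_a`, `freq_b`, `effect` (`freq_a - freq_b`),
#'   `enriched_in` (`"A"`/`"B"`), `p_raw`, `significant`; attributes
#'   `alpha` and `n_tests`.
#' @export
two_sample_logo <- function(group_a, group_b, alpha = 0.05,
                            null = c("pooled", "opposite")) {
  null <- match.arg(null)
  seq_of <- function(g) if (inherits(g, "allele_panel")) g$sequence else
    toupper(as.character(g))
  a <- seq_of(group_a); b <- seq_of(group_b)
  if (length(a) == 0L || length(b) == 0L) stopf("both groups must be non-empty")
  L <- unique(nchar(c(a, b)))
  if (length(L) != 1L) stopf("groups must be aligned to a common length")
  A <- do.call(rbind, strsplit(a, ""))
  B <- do.call(rbind, strsplit(b, ""))
  rows <- list()
  for (p in seq_len(L)) {
    ca <- A[, p]; cb <- B[, p]
    ca <- ca[ca != "*"]; cb <- cb[cb != "*"]
    nA <- length(ca); nB <- length(cb)
    if (nA == 0L || nB == 0L) next
    for (res in sort(unique(c(ca, cb)))) {
      cntA <- sum(ca == res); cntB <- sum(cb == res)
      if (null == "pooled") {
        p_raw <- stats::binom.test(cntA, cntA + cntB,
                                   p = nA / (nA + nB))$p.value
      } else {
        clamp <- function(x) min(max(x, 1e-12), 1 - 1e-12)
        p_raw <- min(
          stats::binom.test(cntA, nA, p = clamp(cntB / nB))$p.value,
          stats::binom.test(cntB, nB, p = clamp(cntA / nA))$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, residue = res,
        freq_a = cntA / nA, freq_b = cntB / nB,
        effect = cntA / nA - cntB / nB,
        p_raw = p_raw, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), residue = character(0),
               freq_a = numeric(0), freq_b = numeric(0), effect = numeric(0),
               p_raw = numeric(0), stringsAsFactors = FALSE)
  n_tests <- nrow(out)
  out$enriched_in <- ifelse(out$effect >= 0, "A", "B")
  out$significant <- out$p_raw < alpha / max(n_tests, 1L)
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- n_tests
  class(out) <- c("logo_result", "data.frame")
  out
}

#' Write a logo result as TSV
#' @param logo a [two_sample_logo()] result.
#' @param path output file.
#' @export
write_logo_tsv <- function(logo, path) {
  utils::write.table(as.data.frame(logo), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
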