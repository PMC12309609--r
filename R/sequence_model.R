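#' Aligned allotype sequence panels
#'
#' An `allele_panel` holds named, pre-aligned amino-acid sequences of HLA
#' class I allotypes (alpha1/alpha2 domains, mature-protein coordinates) or
#' KIR3DL1 allotypes. All sequences in a panel must share one alignment
#' length; positions are 1-based. Unknown residues are written `*`; gap
#' characters (`-`, `.`) in the input are mapped to `*` and treated as
#' unknown downstream.
#'
#' @param name character vector of allele identifiers
#'   (e.g. `"B*57:01"`, `"KIR3DL1*005"`).
#' @param sequence character vector of aligned one-letter amino-acid strings.
#' @param locus optional locus per allele, one of `"A"`, `"B"`, `"C"`,
#'   `"KIR3DL1"`. Defaults to the text before `*` in `name` when that text
#'   is a recognized locus.
#' @return A data frame of class `allele_panel` with columns `name`,
#'   `locus`, `sequence`.
#' @examples
#' allele_panel(c("A*01:01", "B*57:01"), c("RAK", "RGK"))
#' @export
allele_panel <- function(name, sequence, locus = NULL) {
  name <- as.character(name)
  sequence <- toupper(as.character(sequence))
  if (length(name) != length(sequence))
    stopf("`name` and `sequence` must have equal length")
  if (length(name) == 0L) stopf("empty panel")
  if (anyDuplicated(name)) stopf("duplicated allele names in panel")
  sequence <- gsub("[-.]", "*", sequence)
  L <- unique(nchar(sequence))
  if (length(L) != 1L)
    stopf("all sequences must be pre-aligned to one length (found lengths: %s)",
          paste(sort(L), collapse = ", "))
  bad <- grepl(sprintf("[^%s*]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad))
    stopf("sequence for %s contains characters outside the amino-acid alphabet and '*'",
          name[which(bad)[1]])
  if (is.null(locus)) {
    pre <- sub("\\*.*$", "", name)
    locus <- ifelse(pre %in% c("A", "B", "C", "KIR3DL1"), pre, NA_character_)
  }
  locus <- as.character(locus)
  structure(
    data.frame(name = name, locus = locus, sequence = sequence,
               stringsAsFactors = FALSE),
    class = c("allele_panel", "data.frame"))
}

#' @export
print.allele_panel <- function(x, ...) {
  cat(sprintf("allele_panel: %d allotypes, alignment length %d\n",
              nrow(x), panel_length(x)))
  cat(sprintf("loci: %s\n",
              paste(names(table(x$locus, useNA = "ifany")), collapse = " ")))
  invisible(x)
}

#' Alignment length of a panel
#' @param panel an [allele_panel()].
#' @return integer alignment length.
#' @export
panel_length <- function(panel) nchar(panel$sequence[1])

# n x L character matrix of residues
panel_residue_matrix <- function(panel) {
  m <- do.call(rbind, strsplit(panel$sequence, ""))
  rownames(m) <- panel$name
  m
}

# loop ranges on the alpha1/alpha2 domains (1-based inclusive), used by the
# no_loops mask; the helices mask is the complementary structural reading
LOOP_RANGES <- list(c(16, 19), c(39, 44), c(49, 56), c(86, 90), c(106, 107),
                    c(128, 131), c(137, 140), c(151, 152), c(176, 179),
                    c(180, 183))

#' Structurally motivated region masks
#'
#' Four static position sets over the alpha1/alpha2 domains drive the
#' feature encodings: the full domain (`all`), the six Bw4-motif residues
#' `{76, 77, 80, 81, 82, 83}` (`bw4`), the alpha-helices
#' `57..85` and `141..175` (`helices`), and the full domain minus the
#' connecting loops (`no_loops`). Masks are static position sets, never
#' data-dependent; they are clipped to `1..panel_length`.
#'
#' @param name one of `"all"`, `"bw4"`, `"no_loops"`, `"helices"`.
#' @param panel_length alignment length to clip to (default 183, the
#'   alpha1/alpha2 domain span).
#' @return An object of class `region_mask` with fields `name` and
#'   `positions` (sorted integer vector).
#' @examples
#' build_region_mask("bw4")$positions     # 76 77 80 81 82 83
#' length(build_region_mask("helices")$positions)  # 64
#' @export
build_region_mask <- function(name, panel_length = 183L) {
  valid <- c("all", "bw4", "no_loops", "helices")
  if (length(name) != 1L || !name %in% valid)
    stopf("unknown mask name %s; valid names: %s",
          deparse(name), paste(valid, collapse = ", "))
  if (panel_length < 1) stopf("panel_length must be positive")
  loops <- unlist(lapply(LOOP_RANGES, function(r) r[1]:r[2]))
  pos <- switch(name,
    all      = seq_len(panel_length),
    bw4      = c(76L, 77L, 80L, 81L, 82L, 83L),
    helices  = c(57:85, 141:175),
    no_loops = setdiff(seq_len(panel_length), loops))
  pos <- sort(unique(pos[pos >= 1 & pos <= panel_length]))
  structure(list(name = name, positions = as.integer(pos)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask '%s': %d positions\n", x$name, length(x$positions)))
  invisible(x)
}

#' One-hot encode a sequence panel over a region mask
#'
#' Each allotype becomes a binary vector of (position, residue) indicators:
#' an allotype whose masked sequence starts `RA` gets 1 at features `R1` and
#' `A2` and 0 at every other residue option for those positions. Positions
#' invariant across the panel (at most one distinct known residue) carry no
#' information and are removed. Unknown (`*`) residues contribute all-zero
#' indicators at their position. Feature order is deterministic: ascending
#' position, then residue alphabetical.
#'
#' @param panel an [allele_panel()].
#' @param mask a [build_region_mask()] result, or a mask name.
#' @return An object of class `encoded_panel`: list with `matrix`
#'   (n_alleles x n_features binary), `feature_labels` (data frame with
#'   `position`, `residue`, `label`), `allele_names`, `loci`, `mask_name`.
#' @export
one_hot_encode <- function(panel, mask = build_region_mask("all", panel_length(panel))) {
  if (!inherits(panel, "allele_panel")) stopf("`panel` must be an allele_panel")
  if (is.character(mask)) mask <- build_region_mask(mask, panel_length(panel))
  L <- panel_length(panel)
  if (any(mask$positions > L)) stopf("mask positions exceed alignment length %d", L)
  res <- panel_residue_matrix(panel)
  feats <- list()
  for (p in mask$positions) {
    col <- res[, p]
    known <- sort(unique(col[col != "*"]))
    if (length(known) >= 2L)           # invariant positions carry no signal
      feats[[length(feats) + 1L]] <-
        data.frame(position = p, residue = known, stringsAsFactors = FALSE)
  }
  if (length(feats) == 0L) {
    fl <- data.frame(position = integer(0), residue = character(0),
                     label = character(0), stringsAsFactors = FALSE)
    X <- matrix(0, nrow = nrow(panel), ncol = 0,
                dimnames = list(panel$name, NULL))
  } else {
    fl <- do.call(rbind, feats)
    fl$label <- paste0(fl$residue, fl$position)
    X <- matrix(0, nrow = nrow(panel), ncol = nrow(fl),
                dimnames = list(panel$name, fl$label))
    for (j in seq_len(nrow(fl)))
      X[, j] <- as.numeric(res[, fl$position[j]] == fl$residue[j])
  }
  structure(list(matrix = X, feature_labels = fl,
                 allele_names = panel$name, loci = panel$locus,
                 mask_name = mask$name),
            class = "encoded_panel")
}

#' @export
print.encoded_panel <- function(x, ...) {
  cat(sprintf("encoded_panel: %d allotypes x %d features (mask '%s', %d polymorphic positions)\n",
              nrow(x$matrix), ncol(x$matrix), x$mask_name,
              length(unique(x$feature_labels$position))))
  invisible(x)
}

#' Hamming distance between two aligned sequences
#'
#' Count of positions at which two equal-length aligned sequences differ.
#' Used to compare KIR3DL1 allotypes at the protein level.
#'
#' @param a,b character strings (or single-row [allele_panel()] subsets).
#' @return non-negative integer.
#' @examples
#' hamming_distance("RAK", "RGK")  # 1
#' @export
hamming_distance <- function(a, b) {
  if (inherits(a, "allele_panel")) a <- a$sequence
  if (inherits(b, "allele_panel")) b <- b$sequence
  if (length(a) != 1L || length(b) != 1L) stopf("expected single sequences")
  if (nchar(a) != nchar(b))
    stopf("sequences must be aligned to equal length (%d vs %d)",
          nchar(a), nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' All pairwise Hamming distances within a panel
#' @param panel an [allele_panel()].
#' @return a symmetric integer matrix.
#' @export
hamming_matrix <- function(panel) {
  res <- panel_residue_matrix(panel)
  n <- nrow(res)
  d <- matrix(0L, n, n, dimnames = list(panel$name, panel$name))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j) d[i, j] <- d[j, i] <- sum(res[i, ] != res[j, ])
  d
}

#' Epitope motif at positions 80/83
#'
#' Classical serological grouping of class I allotypes by the residues at
#' positions 80 and 83: `I80/R83` and `T80/R83` are Bw4, `N80/G83` is C1,
#' `K80/G83` is C2, and `T80/G83` characterizes the bulk of HLA-A
#' allotypes. Combinations rarer than `min_count` in the panel are labelled
#' `NA` (the rare-combination cutoff is a parameter, not fixed by the
#' method).
#'
#' @param panel an [allele_panel()].
#' @param min_count drop combinations observed fewer than this many times.
#' @return data frame with `name`, `combo` (e.g. `"I80/R83"`), `epitope`.
#' @export
motif_80_83 <- function(panel, min_count = 1L) {
  res <- panel_residue_matrix(panel)
  if (ncol(res) < 83) stopf("panel alignment shorter than position 83")
  combo <- paste0(res[, 80], "80/", res[, 83], "83")
  combo[res[, 80] == "*" | res[, 83] == "*"] <- NA_character_
  tab <- table(combo)
  combo[!is.na(combo) & tab[combo] < min_count] <- NA_character_
  epi <- rep(NA_character_, length(combo))
  epi[combo %in% c("I80/R83", "T80/R83")] <- "Bw4"
  epi[combo == "N80/G83"] <- "C1"
  epi[combo == "K80/G83"] <- "C2"
  data.frame(name = panel$name, combo = combo, epitope = epi,
             stringsAsFactors = FALSE)
}
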