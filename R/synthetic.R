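#' Generate a synthetic aligned allotype panel
#'
#' Builds an aligned panel emulating the polymorphism structure of an HLA
#' class I binding panel: a constant backbone; a Bw4/Bw6-like two-state
#' motif segregating jointly at the `linked_positions` (common and
#' balanced, with rare linkage-breaking flips); common *balanced* binary
#' variation at the `balanced_positions` (the A-pocket contact sites,
#' which in real data carry frequent alternative residues); and
#' independent low-frequency variants at all remaining polymorphic
#' positions. Positions are otherwise independent, so planted effects
#' remain attributable position by position. Loci are assigned A/B/C
#' round-robin; everything is reproducible from the seed.
#'
#' @param n_alleles number of allotypes (default 97, the study panel size).
#' @param length alignment length (default 183, the alpha1/alpha2 span).
#' @param polymorphic_positions positions made polymorphic; the default
#'   plants variation at the Bw4-motif positions 77/80/83, the A-pocket
#'   positions 62/65/66, and a spread of additional helix and loop
#'   positions so every region mask keeps some signal.
#' @param linked_positions positions whose residues segregate jointly as a
#'   two-state motif (default 77/80/83): each allele carries the motif
#'   with probability `link_prob` and then shows the motif residue at each
#'   linked position except for rare `flip_prob` exchanges.
#' @param link_prob motif carrier probability (default 0.6).
#' @param flip_prob per-position probability of breaking the motif linkage.
#' @param balanced_positions positions with common balanced two-residue
#'   variation (default 62/65/66).
#' @param minor_freq total minor-residue frequency at the low-frequency
#'   background positions (default 0.15).
#' @param n_residues residues per background polymorphic position (2 to 4
#'   drawn per position).
#' @param seed RNG seed.
#' @return an [allele_panel()] with attribute `motif_residues` (named
#'   character vector position -> motif residue at the linked positions).
#' @export
generate_panel <- function(n_alleles = 97L, length = 183L,
                           polymorphic_positions = default_polymorphic_positions(length),
                           linked_positions = c(77, 80, 83),
                           link_prob = 0.6, flip_prob = 0.05,
                           balanced_positions = c(62, 65, 66),
                           minor_freq = 0.15, n_residues = 2:4, seed = 1L) {
  if (n_alleles < 2L) stopf("need at least two alleles")
  polymorphic_positions <- sort(unique(polymorphic_positions))
  if (any(polymorphic_positions > length)) stopf("polymorphic position beyond alignment")
  linked_positions <- intersect(linked_positions, polymorphic_positions)
  balanced_positions <- setdiff(intersect(balanced_positions, polymorphic_positions),
                                linked_positions)
  with_seed(seed, {
    backbone <- sample(AA_ALPHABET, length, replace = TRUE)
    res <- matrix(rep(backbone, each = n_alleles), nrow = n_alleles)
    motif_res <- character(0)
    motif <- stats::runif(n_alleles) < link_prob
    for (p in polymorphic_positions) {
      k <- if (base::length(n_residues) == 1L) n_residues
           else sample(n_residues, 1L)
      if (k < 2L) stopf("polymorphic positions need at least two residues")
      alpha <- sample(AA_ALPHABET, k)
      if (p %in% linked_positions) {
        motif_res[as.character(p)] <- alpha[1]
        carrier <- xor(motif, stats::runif(n_alleles) < flip_prob)
        res[, p] <- ifelse(carrier, alpha[1],
                           sample(alpha[-1], n_alleles, replace = TRUE))
      } else if (p %in% balanced_positions) {
        res[, p] <- sample(alpha[1:2], n_alleles, replace = TRUE)
      } else {
        wts <- c(1 - minor_freq, rep(minor_freq / (k - 1), k - 1))
        res[, p] <- sample(alpha, n_alleles, replace = TRUE, prob = wts)
      }
      # guarantee the position really is polymorphic at any n
      if (base::length(unique(res[, p])) == 1L)
        res[1, p] <- setdiff(alpha, res[1, p])[1]
    }
    loci <- rep_len(c("A", "B", "C"), n_alleles)
    nm <- sprintf("%s*SYN:%03d", loci, seq_len(n_alleles))
    out <- allele_panel(nm, apply(res, 1, paste, collapse = ""), loci)
    attr(out, "motif_residues") <- motif_res
    out
  })
}

#' @rdname generate_panel
#' @export
default_polymorphic_positions <- function(length = 183L) {
  pos <- c(62, 65, 66, 77, 80, 83,              # planted signal sites
           17, 41, 50, 59, 63, 67, 70, 71, 76, 79, 81, 82, 88, 94,
           103, 109, 116, 129, 138, 144, 147, 152, 156, 163, 171, 178)
  pos[pos <= length]
}

#' Planted log-linear binding model
#'
#' Defines the ground truth for synthetic binding data. Signal sits on two
#' groups of positions, mirroring the biology the generator emulates:
#' `binder_positions` (default 77/80/83, the Bw4-like motif) carry a large
#' effect `+effect_scale` for the motif residue and 0 otherwise, so the
#' noiseless log binding is bimodal and separates binders from
#' non-binders; `strength_positions` (default 62/65/66, the A-pocket
#' sites) carry moderate mean-zero per-residue effects, evenly spaced over
#' `[-0.5, 0.5] * effect_scale` and randomly assigned to the residues, so
#' every strength position has an identifiable residue contrast; they
#' grade binders into high and low. Per-KIR beta vectors are a common base scaled by a factor
#' uniform in `[0.8, 1.2]`. Class thresholds sit on the log scale at the
#' construction's natural boundaries: non/low at `1.5 * effect_scale`
#' (inside the motif gap) and low/high at a midpoint between distinct
#' binder score values nearest their median (so both strength classes are
#' non-empty by construction); classes are determined by sequence alone.
#'
#' @param panel the [allele_panel()] the model is planted on.
#' @param binder_positions motif positions separating binders from
#'   non-binders; if the panel carries a `motif_residues` attribute (see
#'   [generate_panel()]) the motif residues are taken from it, otherwise
#'   the alphabetically first residue at each position is used.
#' @param strength_positions positions grading binding strength.
#' @param n_kir number of KIR allotypes (default 9, the study panel).
#' @param effect_scale motif effect on the natural-log binding scale
#'   (default 2).
#' @param sigma replicate noise SD on the log scale (default 0.3).
#' @param seed RNG seed.
#' @return an object of class `planted_model` with the true beta vectors
#'   (`betas`: feature x KIR matrix), the shared `base` betas,
#'   `kir_names`, `sigma`, `thresholds`, `signal_positions` and the
#'   encoding used.
#' @export
planted_model <- function(panel, binder_positions = c(77, 80, 83),
                          strength_positions = c(62, 65, 66),
                          n_kir = 9L, effect_scale = 2, sigma = 0.3,
                          seed = 1L) {
  enc <- one_hot_encode(panel)
  fl <- enc$feature_labels
  signal_positions <- c(binder_positions, strength_positions)
  if (!any(fl$position %in% binder_positions))
    stopf("no polymorphic binder positions in the panel")
  kir_names <- sprintf("KIR3DL1*%03d", seq_len(n_kir))
  motif_res <- attr(panel, "motif_residues")
  with_seed(seed, {
    base <- numeric(nrow(fl))
    for (p in intersect(binder_positions, fl$position)) {
      at <- which(fl$position == p)
      fav <- motif_res[as.character(p)] %||% NA_character_
      if (is.na(fav) || !fav %in% fl$residue[at])
        fav <- sort(fl$residue[at])[1]
      base[at[fl$residue[at] == fav]] <- effect_scale
    }
    for (p in intersect(strength_positions, fl$position)) {
      at <- which(fl$position == p)
      k <- base::length(at)
      base[at] <- effect_scale * seq(-0.5, 0.5, length.out = k)[sample(k)]
    }
    scale_k <- stats::runif(n_kir, 0.8, 1.2)
    betas <- outer(base, scale_k)
    rownames(betas) <- fl$label; colnames(betas) <- kir_names
    mean_score <- as.numeric(enc$matrix %*% base)
    thr1 <- 1.5 * effect_scale
    binder_scores <- mean_score[mean_score > thr1]
    if (length(binder_scores) < 2L || all(mean_score > thr1))
      stopf("thresholds produce an empty class; adjust panel or effect_scale")
    # split the binders at a midpoint between their distinct score values
    # (nearest the median), so high and low are both non-empty by construction
    uq <- sort(unique(binder_scores))
    if (length(uq) < 2L)
      stopf("thresholds produce an empty class; binders are degenerate")
    k <- max(1L, which.min(abs(uq[-length(uq)] - stats::median(binder_scores))))
    thr2 <- (uq[k] + uq[k + 1]) / 2
    thr <- c(non_low = thr1, low_high = thr2)
    structure(list(betas = betas, base = base, kir_names = kir_names,
                   sigma = sigma, thresholds = thr,
                   signal_positions = signal_positions,
                   binder_positions = binder_positions,
                   strength_positions = strength_positions,
                   effect_scale = effect_scale,
                   feature_labels = fl, seed = seed),
              class = "planted_model")
  })
}

#' Generate replicate binding runs from a planted model
#'
#' Log binding of allele `h` to KIR `k` is `beta_k . x_h` plus Gaussian
#' noise per replicate; runs are exponentiated raw bead values ready for
#' [aggregate_replicates()]. True three-class labels follow the planted
#' thresholds on the noiseless mean score.
#'
#' @param panel the [allele_panel()] the model was planted on.
#' @param model a [planted_model()].
#' @param n_replicates number of replicate runs (default 3, the assay's
#'   run count).
#' @param seed RNG seed for the noise draws.
#' @return list with `runs` (list of kir x hla matrices), `true_class`
#'   (named factor high/low/non), `true_scores` (noiseless per-KIR log
#'   binding, kir x hla), `model`.
#' @export
generate_binding <- function(panel, model, n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(model, "planted_model"))
  enc <- one_hot_encode(panel)
  if (!identical(enc$feature_labels$label, model$feature_labels$label))
    stopf("panel does not match the planted model's encoding")
  scores <- t(enc$matrix %*% model$betas)       # kir x hla, log scale
  colnames(scores) <- panel$name; rownames(scores) <- model$kir_names
  mean_score <- as.numeric(enc$matrix %*% model$base)
  cls <- cut(mean_score, c(-Inf, model$thresholds, Inf),
             labels = c("non", "low", "high"))
  cls <- factor(stats::setNames(as.character(cls), panel$name),
                levels = c("high", "low", "non"))
  if (any(table(cls) == 0L)) stopf("thresholds produce an empty class")
  runs <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    noise <- matrix(stats::rnorm(length(scores), 0, model$sigma),
                    nrow(scores), ncol(scores))
    m <- exp(scores - max(scores) + noise)      # shift keeps exp() in range
    dimnames(m) <- dimnames(scores)
    m
  }))
  list(runs = runs, true_class = cls, true_scores = scores, model = model)
}

#' Planted three-block normalized binding matrix
#'
#' Direct generator of a normalized-scale matrix with three HLA blocks of
#' prescribed mean binding, used to exercise the clustering taxonomy: a
#' block structure with between-block separation well above the
#' within-block noise is recovered exactly by the three-way cut.
#'
#' @param n_hla,n_kir matrix dimensions.
#' @param means per-block mean binding on the 0-100 scale
#'   (high/low/non, default 90/35/2).
#' @param sigma within-block noise SD.
#' @param props block proportions.
#' @param seed RNG seed.
#' @return list with `matrix` (a [binding_matrix()], stage
#'   `"normalized"`) and `true_class` (named factor).
#' @export
generate_block_matrix <- function(n_hla = 60L, n_kir = 9L,
                                  means = c(high = 90, low = 35, non = 2),
                                  sigma = 3, props = c(0.25, 0.35, 0.40),
                                  seed = 1L) {
  with_seed(seed, {
    n_per <- pmax(1L, round(n_hla * props))
    n_per[3] <- n_hla - sum(n_per[1:2])
    cls <- rep(names(means), n_per)
    v <- matrix(stats::rnorm(n_kir * n_hla, rep(means[cls], each = n_kir),
                             sigma), n_kir, n_hla)
    v <- pmin(pmax(v, 0), 100)
    dimnames(v) <- list(sprintf("KIR3DL1*%03d", seq_len(n_kir)),
                        sprintf("H%03d", seq_len(n_hla)))
    list(matrix = binding_matrix(v, stage = "normalized"),
         true_class = factor(stats::setNames(cls, colnames(v)),
                             levels = c("high", "low", "non")))
  })
}

#' Generate a Dirichlet-like allele-frequency table
#'
#' Positive frequencies summing to one, drawn from a symmetric Dirichlet
#' (gamma draws normalized). Higher concentration gives flatter tables.
#'
#' @param n_alleles number of alleles.
#' @param concentration Dirichlet concentration parameter (default 1).
#' @param locus,population table labels.
#' @param seed RNG seed.
#' @return a [frequency_table()].
#' @export
generate_frequencies <- function(n_alleles, concentration = 1,
                                 locus = "A", population = "SYN", seed = 1L) {
  with_seed(seed, {
    g <- stats::rgamma(n_alleles, shape = concentration)
    g <- pmax(g, .Machine$double.xmin)
    frequency_table(stats::setNames(g / sum(g),
                                    sprintf("%s*SYN:%03d", locus, seq_len(n_alleles))),
                    population = population, locus = locus)
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items;
#' 1 means identical partitions. Used to verify recovery of planted block
#' structure.
#'
#' @param a,b two partitions (vectors of labels, same length).
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions differ in length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  exp_ind <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == exp_ind) return(1)
  (sij - exp_ind) / (mx - exp_ind)
}
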