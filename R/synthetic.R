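# Synthetic cohort generators carrying planted truth. The default scenario
# emulates the structure the pipeline assumes: a 74-sample familial breast
# cancer cohort whose samples follow five intrinsic-subtype expression
# centroids plus a small molecular-apocrine group over-expressing a block
# of ~84 genes; quadruplicate-spotted BAC-clone aCGH profiles with planted
# gains/losses/amplicons; and IHC score tables with per-marker positivity
# probabilities.

.subtypes <- c("basal", "her2", "luminalA", "luminalB", "normal")

#' Generate a synthetic expression cohort with planted structure
#'
#' Probe values are `baseline + class offset + apocrine-block offset +
#' Gaussian noise` on the log2 scale. Each of the five intrinsic subtypes
#' over-expresses its own disjoint block of `class_block` probes by
#' `effect`; apocrine samples over-express a further block of
#' `apocrine_block` probes (and under-express `apocrine_down` probes).
#' Control probes (AFFX-prefixed, flagged in the annotation) are appended
#' with low intensity. A matching subtype centroid set (class mean
#' expression over the class-block genes, symbol namespace) is emitted.
#' Fully determined by `seed`.
#'
#' @param n_samples cohort size (default 74).
#' @param n_probes number of regular probes (default 20000).
#' @param class_proportions named proportions of the five subtypes among
#'   non-apocrine samples; must sum to 1.
#' @param n_apocrine number of molecular-apocrine samples (default 5).
#' @param n_cowden how many apocrine samples carry a germline PTEN mutation
#'   (default 3); these are flagged `cowden` in the sample annotation.
#' @param apocrine_block probes over-expressed in apocrine samples
#'   (default 84).
#' @param apocrine_down probes under-expressed in apocrine samples
#'   (default 0).
#' @param class_block probes per subtype block (default 100).
#' @param effect log2 offset of every planted block (default 2).
#' @param noise_sd Gaussian noise SD on the log2 scale (default 0.5).
#' @param n_controls AFFX control probes appended (default 100).
#' @param seed RNG seed.
#' @return list with `expression`, `annotation`, `samples` (sample
#'   annotation), `centroids`, and `truth` (classes, planted probe blocks,
#'   parameters).
#' @export
generate_expression <- function(n_samples = 74L, n_probes = 20000L,
                                class_proportions = c(basal = 0.20,
                                                      her2 = 0.15,
                                                      luminalA = 0.35,
                                                      luminalB = 0.20,
                                                      normal = 0.10),
                                n_apocrine = 5L, n_cowden = 3L,
                                apocrine_block = 84L, apocrine_down = 0L,
                                class_block = 100L, effect = 2,
                                noise_sd = 0.5, n_controls = 100L, seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  n_structured <- length(.subtypes) * class_block + apocrine_block + apocrine_down
  if (n_structured > n_probes)
    stop("planted blocks larger than the probe count")
  if (n_cowden > n_apocrine) stop("n_cowden cannot exceed n_apocrine")
  set.seed(seed)

  probe_ids <- sprintf("P%05d", seq_len(n_probes))
  ctrl_ids <- sprintf("AFFX-C%03d", seq_len(n_controls))
  sample_ids <- sprintf("T%03d", seq_len(n_samples))

  # planted blocks occupy the first probes, in a fixed layout
  blocks <- split(seq_len(length(.subtypes) * class_block),
                  rep(seq_along(.subtypes), each = class_block))
  names(blocks) <- .subtypes
  apo_up <- seq_len(apocrine_block) + length(.subtypes) * class_block
  apo_dn <- if (apocrine_down > 0)
    seq_len(apocrine_down) + max(apo_up) else integer()

  # class assignment: apocrine samples first, then subtypes by proportion
  n_rest <- n_samples - n_apocrine
  counts <- floor(class_proportions * n_rest)
  rem <- n_rest - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  classes <- c(rep("apocrine", n_apocrine),
               rep(names(counts), times = counts))
  cowden <- c(rep(TRUE, n_cowden), rep(FALSE, n_samples - n_cowden))

  baseline <- stats::runif(n_probes, 9, 13)
  structured <- c(unlist(blocks, use.names = FALSE), apo_up, apo_dn)
  baseline[structured] <- stats::runif(length(structured), 10.5, 12.5)

  M <- matrix(stats::rnorm(n_probes * n_samples, 0, noise_sd),
              nrow = n_probes) + baseline
  for (s in .subtypes)
    M[blocks[[s]], classes == s] <- M[blocks[[s]], classes == s] + effect
  M[apo_up, classes == "apocrine"] <- M[apo_up, classes == "apocrine"] + effect
  if (length(apo_dn))
    M[apo_dn, classes == "apocrine"] <- M[apo_dn, classes == "apocrine"] - effect

  ctrl <- matrix(stats::rnorm(n_controls * n_samples, 0, noise_sd),
                 nrow = n_controls) + stats::runif(n_controls, 6, 8)
  X <- rbind(M, ctrl)
  dimnames(X) <- list(c(probe_ids, ctrl_ids), sample_ids)

  annotation <- data.frame(
    probe_id = rownames(X),
    gene_symbol = c(sprintf("G%05d", seq_len(n_probes)),
                    rep("", n_controls)),
    unigene_id = c(sprintf("Hs.%05d", seq_len(n_probes)),
                   rep("", n_controls)),
    entrez_id = c(as.character(seq_len(n_probes)), rep("", n_controls)),
    is_control = c(rep(FALSE, n_probes), rep(TRUE, n_controls)),
    stringsAsFactors = FALSE)

  samples <- data.frame(
    sample_id = sample_ids,
    cowden_status = ifelse(cowden, "cowden", "non_cowden"),
    germline_mutation = ifelse(cowden, "PTEN c.209+5G>A", ""),
    true_class = classes, stringsAsFactors = FALSE)

  # centroid set over the class-block genes: expected class mean expression
  cent_idx <- unlist(blocks, use.names = FALSE)
  cent <- vapply(.subtypes, function(s) {
    baseline[cent_idx] + effect * (cent_idx %in% blocks[[s]])
  }, numeric(length(cent_idx)))
  rownames(cent) <- annotation$gene_symbol[cent_idx]
  attr(cent, "namespace") <- "symbol"

  truth <- list(classes = stats::setNames(classes, sample_ids),
                cowden = stats::setNames(cowden, sample_ids),
                apocrine_samples = sample_ids[classes == "apocrine"],
                apocrine_up_probes = probe_ids[apo_up],
                apocrine_down_probes = probe_ids[apo_dn],
                class_probes = lapply(blocks, function(i) probe_ids[i]),
                params = list(n_samples = n_samples, n_probes = n_probes,
                              effect = effect, noise_sd = noise_sd,
                              seed = seed))
  list(expression = X, annotation = annotation, samples = samples,
       centroids = cent, truth = truth)
}

#' Approximate human autosome lengths and centromere positions
#'
#' Megabase-resolution coordinates for chromosomes 1-22, suitable for
#' arm-level summaries and synthetic genomes.
#'
#' @return data.frame with `chromosome`, `centromere`, `length` (bp).
#' @export
default_centromeres <- function() {
  len <- c(247, 243, 199, 191, 181, 171, 159, 146, 140, 135, 134, 132,
           114, 106, 100, 89, 79, 76, 63, 62, 47, 50) * 1e6
  cen <- c(125, 93, 91, 50, 48, 61, 60, 45, 49, 40, 53, 35,
           17, 17, 19, 37, 24, 17, 26, 28, 13, 15) * 1e6
  data.frame(chromosome = as.character(1:22), centromere = cen,
             length = len, stringsAsFactors = FALSE)
}

.default_acgh_segments <- function(tumor_ids, map) {
  # planted scenario: mostly flat profiles with a few arm-level or focal
  # events, echoing low-perturbation apocrine genomes plus one
  # amplicon-bearing tumour
  seg <- function(tumor, chrom, start, end, ratio)
    data.frame(tumor_id = tumor, chromosome = as.character(chrom),
               start = start, end = end, ratio = ratio,
               stringsAsFactors = FALSE)
  q_arm <- function(chrom) {
    r <- map[map$chromosome == as.character(chrom), ]
    c(r$centromere + 1, r$length)
  }
  p_arm <- function(chrom) {
    r <- map[map$chromosome == as.character(chrom), ]
    c(1, r$centromere)
  }
  pieces <- list(
    seg(tumor_ids[1], 16, q_arm(16)[1], q_arm(16)[2], 0.5),
    seg(tumor_ids[1], 19, p_arm(19)[1], p_arm(19)[2], 1.5),
    seg(tumor_ids[2], 10, 89e6, 90e6, 0.5),
    seg(tumor_ids[3], 1, q_arm(1)[1], q_arm(1)[2], 1.5),
    seg(tumor_ids[3], 8, p_arm(8)[1], p_arm(8)[2], 0.5),
    seg(tumor_ids[3], 10, 89e6, 90e6, 0.5),
    seg(tumor_ids[4], 17, 35e6, 38e6, 3.0),
    seg(tumor_ids[4], 1, q_arm(1)[1], q_arm(1)[2], 1.5),
    seg(tumor_ids[4], 8, q_arm(8)[1], q_arm(8)[2], 1.5),
    seg(tumor_ids[4], 15, q_arm(15)[1], q_arm(15)[2], 0.5),
    seg(tumor_ids[5], 1, p_arm(1)[1], p_arm(1)[2], 0.5),
    seg(tumor_ids[5], 8, q_arm(8)[1], q_arm(8)[2], 1.5),
    seg(tumor_ids[5], 16, q_arm(16)[1], q_arm(16)[2], 0.5),
    seg(tumor_ids[5], 21, p_arm(21)[1], q_arm(21)[2], 1.5))
  do.call(rbind, pieces[seq_len(min(length(pieces),
                                    ifelse(length(tumor_ids) >= 5, 14, 4)))])
}

#' Generate a synthetic aCGH experiment with planted copy-number events
#'
#' Clones are laid out evenly along 22 autosomes; each tumour's true
#' clone-level ratio is 1 except inside its planted segments. Spot ratios
#' are the true ratio under multiplicative log-normal noise (`sd` on the
#' log2 scale); a stated fraction of spots is given low signal-to-noise so
#' the QC filters have work to do. The planted truth records each tumour's
#' per-arm altered fraction and overall perturbation rate.
#'
#' @param n_clones number of BAC clones (default 5878).
#' @param n_tumors number of tumours (default 5).
#' @param segments data.frame (`tumor_id`, `chromosome`, `start`, `end`,
#'   `ratio`) of planted events; `NULL` uses a built-in low-perturbation
#'   scenario. Segments must lie inside their chromosome and not overlap
#'   within a tumour/chromosome.
#' @param noise_sd log2-scale spot noise SD (default 0.05).
#' @param low_snr_frac fraction of spots given snr below 3 (default 0.02).
#' @param n_spots replicate spots per clone (default 4).
#' @param centromere_map chromosome map (default [default_centromeres()]).
#' @param seed RNG seed.
#' @return list with `experiment` (an `acgh_experiment`), `centromeres`,
#'   and `truth` (per-tumour per-arm altered fractions, overall rates,
#'   true clone status).
#' @export
generate_acgh <- function(n_clones = 5878L, n_tumors = 5L, segments = NULL,
                          noise_sd = 0.05, low_snr_frac = 0.02,
                          n_spots = 4L, centromere_map = default_centromeres(),
                          seed = 1L) {
  set.seed(seed)
  map <- centromere_map
  tumor_ids <- sprintf("S%d", seq_len(n_tumors))
  if (is.null(segments)) segments <- .default_acgh_segments(tumor_ids, map)
  segments$chromosome <- as.character(segments$chromosome)
  for (i in seq_len(nrow(segments))) {
    r <- map[map$chromosome == segments$chromosome[i], ]
    if (nrow(r) == 0L || segments$start[i] < 1 || segments$end[i] > r$length)
      stop("segment outside chromosome: row ", i)
  }
  by_tc <- split(segments, paste(segments$tumor_id, segments$chromosome))
  for (g in by_tc) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)]))
      stop("overlapping segments within a tumour/chromosome")
  }

  # even clone layout proportional to chromosome length
  raw <- n_clones * map$length / sum(map$length)
  n_per <- floor(raw)
  shortfall <- n_clones - sum(n_per)
  if (shortfall > 0) {
    top <- order(raw - n_per, decreasing = TRUE)[seq_len(shortfall)]
    n_per[top] <- n_per[top] + 1L
  }
  clones <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    pos <- round(seq(1e6, map$length[i] - 1e6, length.out = n_per[i]))
    data.frame(chromosome = map$chromosome[i], position = pos,
               stringsAsFactors = FALSE)
  }))
  clones$clone_id <- sprintf("BAC%05d", seq_len(nrow(clones)))
  clones <- clones[, c("clone_id", "chromosome", "position")]

  true_ratio <- matrix(1, nrow = nrow(clones), ncol = n_tumors,
                       dimnames = list(clones$clone_id, tumor_ids))
  for (i in seq_len(nrow(segments))) {
    sel <- clones$chromosome == segments$chromosome[i] &
      clones$position >= segments$start[i] &
      clones$position <= segments$end[i]
    true_ratio[sel, segments$tumor_id[i]] <- segments$ratio[i]
  }

  n_rows <- nrow(clones) * n_tumors * n_spots
  spots <- data.frame(
    clone_id = rep(clones$clone_id, times = n_tumors * n_spots),
    tumor_id = rep(rep(tumor_ids, each = nrow(clones)), times = n_spots),
    stringsAsFactors = FALSE)
  tr <- rep(as.vector(true_ratio), times = n_spots)
  spot_ratio <- tr * 2^stats::rnorm(n_rows, 0, noise_sd)
  cy5 <- stats::runif(n_rows, 500, 1500)
  spots$cy3 <- spot_ratio * cy5
  spots$cy5 <- cy5
  snr <- stats::runif(n_rows, 5, 50)
  low <- stats::runif(n_rows) < low_snr_frac
  snr[low] <- stats::runif(sum(low), 0.5, 2.9)
  spots$snr <- snr
  spots$valid <- TRUE

  experiment <- structure(list(clones = clones, spots = spots),
                          class = "acgh_experiment")

  cen <- map$centromere[match(clones$chromosome, map$chromosome)]
  arm <- paste0(clones$chromosome, ifelse(clones$position < cen, "p", "q"))
  altered <- true_ratio != 1
  per_arm <- apply(altered, 2L, function(a) tapply(a, arm, mean))
  rates <- colMeans(per_arm)
  truth <- list(true_ratio = true_ratio,
                true_status = apply(true_ratio, 2L, call_status),
                per_arm_altered = per_arm,
                rates = rates,
                segments = segments,
                params = list(noise_sd = noise_sd,
                              low_snr_frac = low_snr_frac,
                              n_spots = n_spots, seed = seed))
  list(experiment = experiment, centromeres = map, truth = truth)
}

.default_ihc_probs <- function() {
  markers <- c("AR", "ER", "PR", "ERBB2", "GCDFP15", "GGT1", "PTEN", "EGFR")
  m <- rbind(cowden   = c(1.00, 0.73, 0.73, 0.07, 0.53, 0.80, 0.13, 0.27),
             apocrine = c(1.00, 0.00, 0.00, 0.20, 1.00, 1.00, 1.00, 1.00),
             control  = c(0.70, 0.70, 0.60, 0.15, 0.20, 0.015, 0.96, 0.10))
  colnames(m) <- markers
  m
}

#' Generate a synthetic IHC score table
#'
#' Per sample and marker a positivity indicator is drawn with the group's
#' probability, then translated into the scoring system: a percentage of
#' positive cells drawn uniformly within the score band, the implied 0/1/2
#' score, a staining intensity, and (for ERBB2) a Herceptest reading.
#'
#' @param group_sizes named integer vector of group sizes (default the
#'   cohort-like `c(cowden = 15, apocrine = 5, control = 69)`).
#' @param positivity_probs marker-by-group probability matrix (rows =
#'   groups); default [.default_ihc_probs()]-style cohort values.
#' @param seed RNG seed.
#' @return list with `table` (wide per-tumour table readable by
#'   [marker_counts()]), `detail` (long rows with percent, intensity,
#'   score), and `truth` (the probability matrix and group sizes).
#' @export
generate_ihc <- function(group_sizes = c(cowden = 15L, apocrine = 5L,
                                         control = 69L),
                         positivity_probs = NULL, seed = 1L) {
  set.seed(seed)
  probs <- if (is.null(positivity_probs)) .default_ihc_probs() else positivity_probs
  if (any(probs < 0 | probs > 1)) stop("positivity probabilities must lie in [0, 1]")
  groups <- rep(names(group_sizes), times = group_sizes)
  n <- length(groups)
  sample_ids <- sprintf("I%03d", seq_len(n))
  markers <- colnames(probs)
  detail <- list()
  wide <- data.frame(sample_id = sample_ids,
                     cowden_disease = ifelse(groups == "cowden", "Yes", "No"),
                     group = groups, stringsAsFactors = FALSE)
  for (mk in markers) {
    pos <- stats::runif(n) < probs[match(groups, rownames(probs)), mk]
    if (mk == "ERBB2") {
      hercep <- ifelse(pos, "+++",
                       sample(c("0", "+", "++"), n, replace = TRUE,
                              prob = c(0.8, 0.15, 0.05)))
      wide[[mk]] <- hercep
      detail[[mk]] <- data.frame(sample_id = sample_ids, group = groups,
                                 marker = mk, percent_positive = NA_real_,
                                 intensity = NA_integer_, score = NA_integer_,
                                 herceptest = hercep, stringsAsFactors = FALSE)
      next
    }
    if (mk %in% c("ER", "PR", "AR")) {
      pct <- ifelse(pos, stats::runif(n, 11, 100),
                    ifelse(stats::runif(n) < 0.5, 0, stats::runif(n, 1, 10)))
    } else {
      pct <- ifelse(pos, stats::runif(n, 1, 100), 0)
    }
    score <- score_from_percent(pct)
    wide[[mk]] <- as.character(score)
    detail[[mk]] <- data.frame(sample_id = sample_ids, group = groups,
                               marker = mk, percent_positive = pct,
                               intensity = sample(1:3, n, replace = TRUE),
                               score = score, herceptest = NA_character_,
                               stringsAsFactors = FALSE)
  }
  list(table = wide, detail = do.call(rbind, detail),
       truth = list(probs = probs, group_sizes = group_sizes, seed = seed))
}
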