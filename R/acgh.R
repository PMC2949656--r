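# Array-CGH calling on replicate-spotted BAC clones: spot QC and
# aggregation, gain/loss/amplicon status, cohort-wide sparse-clone
# exclusion, and the per-arm genomic perturbation rate.

#' Aggregate replicate spots of one clone into a median ratio
#'
#' Spots flagged invalid, with signal-to-noise below `snr_min`, or with
#' non-positive intensities are dropped. If no spot survives, or the
#' standard deviation of the surviving spots' log2 ratios exceeds `sd_max`,
#' the clone is missing (`NA`); otherwise the median of the surviving
#' linear Cy3/Cy5 ratios is returned.
#'
#' @param cy3,cy5 spot intensities (tumour / reference channels).
#' @param snr per-spot signal-to-noise ratio.
#' @param valid per-spot validity flag.
#' @param snr_min minimum signal-to-noise (default 3).
#' @param sd_max maximum replicate log2-ratio SD (default 0.1).
#' @return Median linear ratio, or `NA` when the clone is missing.
#' @export
aggregate_clone <- function(cy3, cy5, snr, valid = TRUE,
                            snr_min = 3, sd_max = 0.1) {
  valid <- rep_len(as.logical(valid), length(cy3))
  ok <- valid & snr >= snr_min & cy3 > 0 & cy5 > 0
  if (!any(ok)) return(NA_real_)
  ratio <- cy3[ok] / cy5[ok]
  if (length(ratio) > 1L && stats::sd(log2(ratio)) > sd_max)
    return(NA_real_)
  stats::median(ratio)
}

#' Aggregate a whole aCGH experiment into a clone-by-tumour ratio matrix
#'
#' Applies [aggregate_clone()] to every clone/tumour combination.
#'
#' @param experiment an `acgh_experiment` (see [read_clone_table()]).
#' @param snr_min,sd_max QC thresholds, see [aggregate_clone()].
#' @return Numeric matrix, clones x tumours, of median linear ratios with
#'   `NA` for missing.
#' @export
aggregate_ratios <- function(experiment, snr_min = 3, sd_max = 0.1) {
  stopifnot(inherits(experiment, "acgh_experiment"))
  sp <- experiment$spots
  ok <- sp$valid & sp$snr >= snr_min & sp$cy3 > 0 & sp$cy5 > 0
  clone_ids <- experiment$clones$clone_id
  tumor_ids <- sort(unique(sp$tumor_id))
  spo <- sp[ok, , drop = FALSE]
  key <- interaction(factor(spo$clone_id, levels = clone_ids),
                     factor(spo$tumor_id, levels = tumor_ids), drop = FALSE)
  ratio <- spo$cy3 / spo$cy5
  lr <- log2(ratio)
  med <- tapply(ratio, key, stats::median)
  nspots <- tapply(ratio, key, length)
  sdlr <- tapply(lr, key, stats::sd)
  out <- matrix(NA_real_, nrow = length(clone_ids), ncol = length(tumor_ids),
                dimnames = list(clone_ids, tumor_ids))
  vals <- as.numeric(med)
  # replicate-SD filter: >1 surviving spot with log2-ratio SD above the cap
  bad <- !is.na(nspots) & nspots > 1L & !is.na(sdlr) & sdlr > sd_max
  vals[bad] <- NA_real_
  out[] <- vals
  out
}

#' Call copy-number status from a median ratio
#'
#' Thresholds are applied on the linear Cy3/Cy5 ratio scale: ratios above
#' `amp` are amplicons, above `gain` are gains, below `loss` are losses,
#' anything else is normal; all comparisons are strict. `literal_log = TRUE`
#' instead applies the same cut-offs to the log2 ratio.
#'
#' @param ratio numeric vector of median ratios (`NA` = missing).
#' @param gain,loss,amp thresholds (defaults 1.2 / 0.8 / 2.0).
#' @param literal_log apply thresholds to `log2(ratio)` verbatim.
#' @return Character vector in
#'   `{"loss", "normal", "gain", "amplicon", "missing"}`.
#' @export
call_status <- function(ratio, gain = 1.2, loss = 0.8, amp = 2.0,
                        literal_log = FALSE) {
  x <- if (literal_log) log2(ratio) else ratio
  out <- rep("normal", length(x))
  out[x > gain] <- "gain"
  out[x > amp] <- "amplicon"
  out[x < loss] <- "loss"
  out[is.na(x)] <- "missing"
  out
}

#' Exclude clones missing in too many tumours
#'
#' Removes, cohort-wide, clones whose aggregated ratio is missing in more
#' than `max_missing_fraction` of tumours (strictly more: a clone missing in
#' exactly half the tumours is kept).
#'
#' @param ratios clone-by-tumour ratio matrix from [aggregate_ratios()].
#' @param max_missing_fraction default 0.5.
#' @return Character vector of retained clone ids.
#' @export
exclude_sparse_clones <- function(ratios, max_missing_fraction = 0.5) {
  if (ncol(ratios) < 1L) stop("need at least one tumour")
  frac <- rowMeans(is.na(ratios))
  rownames(ratios)[frac <= max_missing_fraction]
}

#' Per-arm genomic perturbation rate
#'
#' Assigns each clone to its chromosome arm (p if its position is below the
#' centromere, q otherwise), computes per arm the fraction of informative
#' (non-missing) clones called lost, gained or amplified, and returns the
#' unweighted mean of those fractions over arms with at least one
#' informative clone.
#'
#' @param status character vector of clone statuses (see [call_status()]).
#' @param clones data.frame with `clone_id`, `chromosome`, `position`
#'   aligned with `status`.
#' @param centromere_map data.frame from [read_centromeres()] covering every
#'   chromosome present.
#' @return list with `per_arm` (chromosome, arm, n_informative, n_altered,
#'   fraction) and `rate`, the overall perturbation rate.
#' @export
perturbation_rate <- function(status, clones, centromere_map) {
  stopifnot(length(status) == nrow(clones))
  miss <- setdiff(unique(clones$chromosome), centromere_map$chromosome)
  if (length(miss))
    stop("chromosome(s) absent from the centromere map: ",
         paste(miss, collapse = ", "))
  cen <- centromere_map$centromere[match(clones$chromosome,
                                         centromere_map$chromosome)]
  arm <- ifelse(clones$position < cen, "p", "q")
  informative <- status != "missing"
  altered <- status %in% c("loss", "gain", "amplicon")
  key <- paste0(clones$chromosome, arm)
  n_inf <- tapply(informative, key, sum)
  n_alt <- tapply(altered & informative, key, sum)
  per_arm <- data.frame(
    chromosome = sub("[pq]$", "", names(n_inf)),
    arm = sub("^.*([pq])$", "\\1", names(n_inf)),
    n_informative = as.integer(n_inf),
    n_altered = as.integer(n_alt),
    fraction = ifelse(n_inf > 0, n_alt / n_inf, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  rate <- mean(per_arm$fraction[per_arm$n_informative > 0])
  list(per_arm = per_arm, rate = rate)
}

#' Static genome-wide plot of clone status calls
#'
#' One horizontal track per chromosome with clones coloured by status
#' (gain red, amplicon blue, loss green, normal yellow, missing grey).
#'
#' @param status clone status vector.
#' @param clones clone table aligned with `status`.
#' @param centromere_map centromere/length map for track extents.
#' @param file optional PNG path; when `NULL` draws on the active device.
#' @param main plot title.
#' @export
genome_plot <- function(status, clones, centromere_map, file = NULL,
                        main = "aCGH status calls") {
  cols <- c(gain = "red", amplicon = "blue", loss = "darkgreen",
            normal = "gold", missing = "grey70")
  if (!is.null(file)) {
    grDevices::png(file, width = 1000, height = 700)
    on.exit(grDevices::dev.off())
  }
  chroms <- centromere_map$chromosome
  graphics::plot(NULL, xlim = c(0, max(centromere_map$length)),
                 ylim = c(0.5, length(chroms) + 0.5), yaxt = "n",
                 xlab = "position (bp)", ylab = "", main = main)
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 2,
                 cex.axis = 0.7)
  for (i in seq_along(chroms)) {
    sel <- clones$chromosome == chroms[i]
    graphics::segments(0, i, centromere_map$length[i], i, col = "grey90")
    graphics::points(clones$position[sel], rep(i, sum(sel)), pch = 15,
                     cex = 0.4, col = cols[status[sel]])
    graphics::points(centromere_map$centromere[i], i, pch = 3, cex = 0.8)
  }
  invisible(NULL)
}
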