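# Hypergeometric over-representation testing of a signature against gene-set
# collections, and signature-vs-signature overlap testing.

#' Upper-tail hypergeometric probability, computed in log space
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that
#' drawing `n` genes from a universe of `N` containing `K` set members
#' yields at least `k` members. The tail is summed in log space
#' (log-binomials combined by log-sum-exp) for numerical safety at extreme
#' significance.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n number of draws (signature size within the universe).
#' @param N universe size.
#' @return The tail probability.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  i <- k:min(K, n)
  logs <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logs)
  exp(m + log(sum(exp(logs - m))))
}

.enrich_one <- function(set_members, signature, universe) {
  members <- intersect(set_members, universe)
  overlap <- intersect(members, signature)
  data.frame(set_size = length(members),
             signature_size = length(signature),
             overlap = length(overlap),
             p_value = if (length(members) == 0L) NA_real_ else
               hypergeom_tail(length(overlap), length(members),
                              length(signature), length(universe)),
             overlapping_genes = paste(sort(overlap), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of a signature against a gene-set collection
#'
#' Set members and the signature are both intersected with the universe
#' first; sets disjoint from the universe are dropped with a warning. The
#' raw one-sided hypergeometric p-value is reported per set, with a
#' Benjamini-Hochberg adjusted column added for convenience.
#'
#' @param signature character vector of gene ids.
#' @param sets named list of member vectors (see [read_gene_sets()]).
#' @param universe character vector of gene ids; must contain the signature.
#' @return data.frame sorted by increasing p: `set_name`, `set_size`,
#'   `signature_size`, `overlap`, `p_value`, `p_adjust_bh`,
#'   `overlapping_genes`.
#' @export
enrich_signature <- function(signature, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  signature <- intersect(unique(signature), universe)
  rows <- lapply(names(sets), function(nm)
    cbind(data.frame(set_name = nm, stringsAsFactors = FALSE),
          .enrich_one(sets[[nm]], signature, universe)))
  out <- do.call(rbind, rows)
  empty <- is.na(out$p_value)
  if (any(empty)) {
    warning("dropping set(s) disjoint from the universe: ",
            paste(out$set_name[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  out$p_adjust_bh <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out[, c("set_name", "set_size", "signature_size", "overlap",
          "p_value", "p_adjust_bh", "overlapping_genes")]
}

#' Overlap significance between two signatures
#'
#' Hypergeometric tail probability of observing at least the seen overlap
#' between two gene lists within a common universe.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe character vector of gene ids.
#' @return One-row data.frame as in [enrich_signature()].
#' @export
signature_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  a <- intersect(unique(set_a), universe)
  res <- .enrich_one(set_b, a, universe)
  cbind(data.frame(set_name = "signature_overlap", stringsAsFactors = FALSE),
        res)
}
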