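#' Fraction of homoeolog pairs assigned to the same module
#'
#' Compares the module labels of the A and D copy of each pair within one
#' homoeologous network run. Pairs with either member unassigned (label 0)
#' or absent from the label vector are excluded from the matched count and
#' reported separately; the denominator is switchable.
#'
#' @param labels_A,labels_D named integer module labels for the A and D
#'   copies (typically one `module_assignment$labels` vector indexed by the
#'   two gene columns of `pairing`, or two separate vectors named by pair id).
#' @param pairing pairing table (`gene_A`, `gene_D`, `pair_id`).
#' @param denominator `"assigned"` (both members in a nonzero module;
#'   default), `"expressed"` (both members present in the label vectors), or
#'   `"all"` (every pair in `pairing`).
#' @return List with `fraction`, `n_matched`, `n_assigned`, `n_expressed`,
#'   `n_pairs`, `denominator`.
#' @export
co_module_fraction <- function(labels_A, labels_D, pairing,
                               denominator = c("assigned", "expressed", "all")) {
  denominator <- match.arg(denominator)
  if (nrow(pairing) == 0) stop("empty pairing table", call. = FALSE)
  la <- .pair_labels(labels_A, pairing$gene_A, pairing$pair_id)
  ld <- .pair_labels(labels_D, pairing$gene_D, pairing$pair_id)
  expressed <- !is.na(la) & !is.na(ld)
  assigned <- expressed & la > 0 & ld > 0
  matched <- assigned & la == ld
  denom <- switch(denominator,
                  assigned = sum(assigned),
                  expressed = sum(expressed),
                  all = nrow(pairing))
  list(fraction = if (denom > 0) sum(matched) / denom else NA_real_,
       n_matched = sum(matched), n_assigned = sum(assigned),
       n_expressed = sum(expressed), n_pairs = nrow(pairing),
       denominator = denominator)
}

.pair_labels <- function(labels, genes, pair_ids) {
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  if (all(genes %in% names(labels))) return(unname(labels[genes]))
  if (all(pair_ids %in% names(labels))) return(unname(labels[pair_ids]))
  unname(labels[genes])  # partial coverage: missing genes become NA
}

#' Chi-square test of A/D balance
#'
#' Pearson goodness-of-fit of the observed (A-biased, D-biased) counts
#' against an equal 50/50 expectation, df = 1, no continuity correction.
#'
#' @param n_A,n_D counts of A-biased and D-biased pairs (`n_A + n_D >= 1`).
#' @return List with `statistic`, `p_value`, and `call` (`"A-bias"`,
#'   `"D-bias"` or `"balanced"` at P < 0.05). Both counts zero yields `NA`.
#' @export
chi_square_balance <- function(n_A, n_D) {
  if (n_A + n_D < 1 || is.na(n_A) || is.na(n_D))
    return(list(statistic = NA_real_, p_value = NA_real_, call = NA_character_))
  ct <- suppressWarnings(stats::chisq.test(c(n_A, n_D), correct = FALSE))
  direction <- if (ct$p.value < 0.05) {
    if (n_A > n_D) "A-bias" else if (n_D > n_A) "D-bias" else "balanced"
  } else "balanced"
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       call = direction)
}

#' Per-module homoeolog expression bias table
#'
#' Cross-tabulates the biased pairs of each joint-network module, tests each
#' module's A/D balance with [chi_square_balance()], and appends an overall
#' row summing every biased pair. A module call is made at `p < alpha` in
#' the majority direction. Module 0 (unassigned genes) is included but
#' flagged.
#'
#' @param joint_labels named module labels of the joint (pair) network,
#'   indexed by pair id; a `module_assignment` is accepted.
#' @param bias_classes named per-pair classes from [classify_bias()]
#'   (`"A"`, `"D"`, `"none"`).
#' @param alpha significance level.
#' @return Data frame with columns `module`, `total`, `A_biased`, `D_biased`,
#'   `p_value`, `call`, `unassigned_module` — one row per module plus a
#'   `"sum"` row.
#' @export
module_bias_table <- function(joint_labels, bias_classes, alpha = 0.05) {
  if (inherits(joint_labels, "module_assignment"))
    joint_labels <- joint_labels$labels
  pairs <- intersect(names(joint_labels), names(bias_classes))
  lab <- joint_labels[pairs]
  cls <- bias_classes[pairs]
  mods <- sort(unique(lab))
  rows <- lapply(mods, function(m) {
    in_m <- lab == m
    n_a <- sum(cls[in_m] == "A")
    n_d <- sum(cls[in_m] == "D")
    cs <- chi_square_balance(n_a, n_d)
    dir <- if (n_a > n_d) "A-bias" else if (n_d > n_a) "D-bias" else "balanced"
    adj_call <- if (is.na(cs$p_value)) NA_character_ else
      if (cs$p_value < alpha) dir else "balanced"
    data.frame(module = as.character(m), total = n_a + n_d,
               A_biased = n_a, D_biased = n_d, p_value = cs$p_value,
               call = adj_call, unassigned_module = m == 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_a <- sum(tab$A_biased); n_d <- sum(tab$D_biased)
  cs <- chi_square_balance(n_a, n_d)
  dir <- if (n_a > n_d) "A-bias" else if (n_d > n_a) "D-bias" else "balanced"
  tab <- rbind(tab, data.frame(
    module = "sum", total = n_a + n_d, A_biased = n_a, D_biased = n_d,
    p_value = cs$p_value,
    call = if (!is.na(cs$p_value) && cs$p_value < alpha) dir else "balanced",
    unassigned_module = FALSE, stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  tab
}
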