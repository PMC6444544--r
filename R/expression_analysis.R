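HSF_ORGANS <- c("leaf", "root")
HSF_TREATMENTS <- c("control", "H2O2", "HS", "ABA", "SA", "PEG")

#' Construct a TPM expression set
#'
#' Bundles a genes x samples TPM matrix with per-sample organ/treatment
#' metadata and validates both.
#'
#' @param tpm Numeric matrix (genes in rows, samples in columns), finite and
#'   nonnegative.
#' @param organ Character vector (one per sample) in `{leaf, root}`.
#' @param treatment Character vector (one per sample) in
#'   `{control, H2O2, HS, ABA, SA, PEG}`.
#' @return An object of class `hsf_expr`: list with `tpm` and `samples`
#'   (data frame `sample`, `organ`, `treatment`).
#' @export
expression_set <- function(tpm, organ, treatment) {
  stopifnot(is.matrix(tpm), length(organ) == ncol(tpm),
            length(treatment) == ncol(tpm))
  if (any(!is.finite(tpm)) || any(tpm < 0))
    stop("TPM values must be finite and nonnegative")
  if (!all(organ %in% HSF_ORGANS)) stop("unknown organ label")
  if (!all(treatment %in% HSF_TREATMENTS)) stop("unknown treatment label")
  if (is.null(colnames(tpm)))
    colnames(tpm) <- make.unique(paste(organ, treatment, sep = "_"))
  structure(list(tpm = tpm,
                 samples = data.frame(sample = colnames(tpm), organ = organ,
                                      treatment = treatment,
                                      stringsAsFactors = FALSE)),
            class = "hsf_expr")
}

#' @export
print.hsf_expr <- function(x, ...) {
  cat("hsf_expr:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples\n")
  invisible(x)
}

#' Log2 transform for heatmap display
#'
#' @param m An `hsf_expr` or a nonnegative numeric matrix of TPM values.
#' @param pseudocount Added before the log (default 1, so TPM 0 maps to 0).
#' @return Matrix of `log2(TPM + pseudocount)`.
#' @export
log2_heatmap_matrix <- function(m, pseudocount = 1) {
  tpm <- if (inherits(m, "hsf_expr")) m$tpm else m
  if (any(tpm < 0)) stop("negative TPM")
  log2(tpm + pseudocount)
}

#' Call per-gene treatment responses
#'
#' For each organ, compares every treatment against that organ's control
#' (averaging replicate samples of the same condition). With fold change
#' `FC = (treat + eps) / (ctrl + eps)`: a gene is `up` when
#' `FC >= fc_threshold` and the treated level reaches the expression floor,
#' `down` when `FC <= 1/fc_threshold` and the control reaches the floor,
#' `not_expressed` when both sides are below the floor, otherwise
#' `insensitive`.
#'
#' @param es An `hsf_expr`.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param expression_floor TPM floor below which a gene counts as not
#'   expressed (default 1).
#' @param eps Ratio pseudocount (default 0.01).
#' @return Data frame with `gene`, `organ`, `treatment`, `control_tpm`,
#'   `treatment_tpm`, `fold_change`, `call`.
#' @export
call_responses <- function(es, fc_threshold = 2, expression_floor = 1,
                           eps = 0.01) {
  stopifnot(inherits(es, "hsf_expr"))
  out <- list()
  for (org in unique(es$samples$organ)) {
    ctrl_cols <- es$samples$sample[es$samples$organ == org &
                                   es$samples$treatment == "control"]
    if (length(ctrl_cols) == 0) stop("missing control sample for organ ", org)
    ctrl <- rowMeans(es$tpm[, ctrl_cols, drop = FALSE])
    for (tr in setdiff(unique(es$samples$treatment[es$samples$organ == org]),
                       "control")) {
      cols <- es$samples$sample[es$samples$organ == org &
                                es$samples$treatment == tr]
      treat <- rowMeans(es$tpm[, cols, drop = FALSE])
      fc <- (treat + eps) / (ctrl + eps)
      call <- ifelse(treat < expression_floor & ctrl < expression_floor,
                     "not_expressed",
              ifelse(fc >= fc_threshold & treat >= expression_floor, "up",
              ifelse(fc <= 1 / fc_threshold & ctrl >= expression_floor,
                     "down", "insensitive")))
      out[[length(out) + 1]] <- data.frame(
        gene = rownames(es$tpm), organ = org, treatment = tr,
        control_tpm = unname(ctrl), treatment_tpm = unname(treat),
        fold_change = unname(fc), call = unname(call),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Summarise responses by gene group
#'
#' Aggregates response calls and expression levels per group (class,
#' subclass, or any labelling) for each organ x treatment cell.
#'
#' @param calls Data frame from [call_responses()].
#' @param es The `hsf_expr` the calls were derived from.
#' @param labels Named character vector mapping every gene to its group.
#' @return Data frame with `group`, `organ`, `treatment`, `n`, `mean_log2`
#'   (mean `log2(TPM + 1)` of the treated samples), `pct_up`, `pct_down`,
#'   `all_unexpressed` flag.
#' @export
aggregate_by_group <- function(calls, es, labels) {
  missing <- setdiff(unique(calls$gene), names(labels))
  if (length(missing) > 0) stop("unlabelled gene: ", missing[1])
  calls$group <- unname(labels[calls$gene])
  keys <- unique(calls[, c("group", "organ", "treatment")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- calls[calls$group == k$group & calls$organ == k$organ &
                 calls$treatment == k$treatment, ]
    data.frame(group = k$group, organ = k$organ, treatment = k$treatment,
               n = nrow(sub),
               mean_log2 = mean(log2(sub$treatment_tpm + 1)),
               pct_up = 100 * mean(sub$call == "up"),
               pct_down = 100 * mean(sub$call == "down"),
               all_unexpressed = all(sub$call == "not_expressed"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `ddCt = (Ct_t,target - Ct_t,ref) - (Ct_c,target - Ct_c,ref)` and
#' the fold change `2^-ddCt`. Evaluating the calibrator sample against itself
#' returns exactly 1.
#'
#' @param ct_target_treated,ct_ref_treated Ct values of the target and
#'   reference gene in the treated sample.
#' @param ct_target_control,ct_ref_control Ct values in the calibrator
#'   (control) sample.
#' @return Fold change(s), `2^-ddCt` (vectorised).
#' @export
ddct_fold <- function(ct_target_treated, ct_ref_treated,
                      ct_target_control, ct_ref_control) {
  args <- list(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(vapply(args, function(x) any(is.na(x)) || length(x) == 0,
                 logical(1))))
    stop("all four Ct values are required")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
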