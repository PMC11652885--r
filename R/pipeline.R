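# End-to-end two-step screen: pharmacophore match -> 2D descriptors ->
# SVM retention, plus stage-wise evaluation against truth labels.

#' Run the two-step virtual screen over a compound library
#'
#' Each compound is screened against the pharmacophore model; hits get
#' descriptor coordinates and an SVM verdict. With
#' `descriptor_policy = "fixture"`, descriptor coordinates are taken from a
#' supplied table (e.g. the printed training table) instead of being
#' recomputed — required to reproduce printed campaign numbers exactly.
#'
#' @param library data.frame with `compound_id` (or `id`) and `smiles`.
#' @param pharm `pharm_model` (default the shipped [orco_model()]).
#' @param svm trained `orco_svm`, or `NULL` to stop after the first stage.
#' @param n,seed,dedup_rms conformer ensemble parameters.
#' @param descriptor_policy `"computed"` or `"fixture"`.
#' @param fixture_descriptors data.frame `compound_id`, `kier_a2`,
#'   `slogp_vsa1` used when the policy is `"fixture"`.
#' @param descriptor_params SlogP_VSA1 parameterisation (see [slogp_vsa1()]).
#' @return data.frame of class `screen_report`: per-compound
#'   `pharmacophore_hit`, `kier_a2`, `slogp_vsa1`, `svm_retained`, `error`;
#'   attributes `counts` (stage funnel) and `provenance`.
#' @export
run_screen <- function(library, pharm = orco_model(), svm = NULL,
                       n = 100, seed = 2024, dedup_rms = 0.5,
                       descriptor_policy = c("computed", "fixture"),
                       fixture_descriptors = NULL,
                       descriptor_params = "moe") {
  descriptor_policy <- match.arg(descriptor_policy)
  if (NROW(library) == 0) stop("empty compound library")
  if (!"compound_id" %in% names(library) && "id" %in% names(library)) {
    library$compound_id <- library$id
  }
  stopifnot(all(c("compound_id", "smiles") %in% names(library)))
  nmol <- nrow(library)
  out <- data.frame(
    compound_id = library$compound_id,
    name = if ("name" %in% names(library)) library$name else NA_character_,
    pharmacophore_hit = NA, kier_a2 = NA_real_, slogp_vsa1 = NA_real_,
    svm_retained = NA, error = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nmol)) {
    res <- tryCatch({
      mr <- screen_compound(library$smiles[i], pharm, n = n, seed = seed,
                            dedup_rms = dedup_rms)
      list(hit = mr$matched)
    }, error = function(e) list(err = conditionMessage(e)))
    if (!is.null(res$err)) {
      out$error[i] <- res$err
      next
    }
    out$pharmacophore_hit[i] <- res$hit
    if (!res$hit) next
    desc <- tryCatch({
      if (descriptor_policy == "fixture") {
        row <- fixture_descriptors[
          fixture_descriptors$compound_id == library$compound_id[i], ]
        if (nrow(row) != 1) stop("no fixture descriptors for compound ",
                                 library$compound_id[i])
        c(row$kier_a2, row$slogp_vsa1)
      } else {
        c(kier_alpha2(library$smiles[i]),
          slogp_vsa1(library$smiles[i], params = descriptor_params))
      }
    }, error = function(e) e)
    if (inherits(desc, "error")) {
      out$error[i] <- conditionMessage(desc)
      next
    }
    out$kier_a2[i] <- desc[1]
    out$slogp_vsa1[i] <- desc[2]
    if (!is.null(svm)) {
      out$svm_retained[i] <-
        predict(svm, matrix(desc, nrow = 1)) == "retained"
    }
  }
  if (all(!is.na(out$error))) stop("every compound failed to screen")
  attr(out, "counts") <- list(
    library = nmol,
    pharmacophore_hits = sum(out$pharmacophore_hit, na.rm = TRUE),
    svm_retained = sum(out$svm_retained, na.rm = TRUE))
  attr(out, "provenance") <- list(
    seed = seed, n_conformers = n, dedup_rms = dedup_rms,
    descriptor_policy = descriptor_policy,
    package_version = as.character(utils::packageVersion("orcoscreen")))
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Evaluate screen predictions against truth labels
#'
#' @param predictions named logical vector, or a `screen_report` (stages are
#'   extracted from `pharmacophore_hit` / `svm_retained`).
#' @param truth named logical vector of true activity.
#' @return for a plain vector, a list with `counts` and `metrics`; for a
#'   `screen_report`, one such list per stage (`pharmacophore`, `combined`).
#' @export
run_evaluation <- function(predictions, truth) {
  eval_one <- function(pred) {
    counts <- confusion(pred, truth)
    list(counts = counts, metrics = screen_metrics(counts))
  }
  if (inherits(predictions, "screen_report")) {
    pharm <- stats::setNames(predictions$pharmacophore_hit %in% TRUE,
                             predictions$compound_id)
    out <- list(pharmacophore = eval_one(pharm))
    if (any(!is.na(predictions$svm_retained))) {
      comb <- stats::setNames(predictions$svm_retained %in% TRUE,
                              predictions$compound_id)
      out$combined <- eval_one(comb)
    }
    out
  } else {
    eval_one(predictions)
  }
}
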