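#' Pipeline stages: pools to trained ensemble to designed peptides
#'
#' These functions chain the package's modules into the full workflow —
#' build pools, split, train the ensemble, validate it, design candidates,
#' evaluate designs — with every stage writing plain-text outputs plus a
#' JSON run manifest (configuration snapshot, seeds, input digests, output
#' paths) so a run can be reproduced exactly. The thin command-line wrapper
#' in `inst/cli/pepdesign.R` exposes the same stages as subcommands
#' (`synth | train | predict | design | evaluate | diversity`).
#'
#' @name pipeline
NULL

write_manifest <- function(path, stage, config, inputs = character(0),
                           outputs = character(0)) {
  digest <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    sprintf("size:%d", file.info(f)$size)
  }
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("pepdesign")),
    config = config,
    inputs = lapply(stats::setNames(as.list(inputs), inputs), digest),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Train-and-validate pipeline stage
#'
#' Builds pools from a training table, trains the ensemble, and — when a
#' test table is given — writes a per-member AUROC/AUPR validation report
#' with the ensemble row computed from the combined posterior.
#'
#' @param train_records Labeled training records (both pools).
#' @param test_records Optional held-out records for the report.
#' @param specs Member specs (default [default_member_specs()]).
#' @param seed Integer seed.
#' @param tau Decision threshold.
#' @param dock_scores Optional docking scores (train + test ids).
#' @param out_dir Output directory for the model bundle, report and
#'   manifest; `NULL` skips writing.
#' @return List: `model`, `report` (`data.frame` or `NULL`).
#' @export
run_training_pipeline <- function(train_records, test_records = NULL,
                                  specs = default_member_specs(),
                                  seed = 1L, tau = 0.5, dock_scores = NULL,
                                  out_dir = NULL) {
  model <- train_ensemble(train_records, specs, seed = seed, tau = tau,
                          dock_scores = dock_scores)
  report <- NULL
  if (!is.null(test_records)) {
    pred <- predict_ensemble(model, test_records, dock_scores = dock_scores)
    labels <- test_records$label == "positive"
    rows <- lapply(colnames(pred$member_probs), function(nm) {
      data.frame(member = nm, weight = model$weights[[nm]],
                 auroc = auroc(pred$member_probs[, nm], labels),
                 aupr = aupr(pred$member_probs[, nm], labels))
    })
    rows <- c(rows, list(data.frame(member = "ensemble", weight = NA_real_,
                                    auroc = auroc(pred$ensemble, labels),
                                    aupr = aupr(pred$ensemble, labels))))
    report <- do.call(rbind, rows)
    rownames(report) <- NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(model, file.path(out_dir, "ensemble_model.rds"))
    if (!is.null(report)) {
      utils::write.table(report, file.path(out_dir, "validation_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(file.path(out_dir, "manifest.json"), "train",
                   list(seed = seed, tau = tau,
                        members = names(model$members),
                        weights = as.list(model$weights)),
                   outputs = file.path(out_dir, c("ensemble_model.rds",
                                                  "validation_report.tsv")))
  }
  list(model = model, report = report)
}

#' Design pipeline stage
#'
#' Runs [run_design_campaign()] and re-verifies every emitted candidate with
#' the independent naive constraint checker before writing; any violation
#' aborts (it would indicate a walker bug).
#'
#' @param train_records Training records with intensities.
#' @param test_sequences Withheld test-set sequences.
#' @param model Trained ensemble.
#' @param out_dir Output directory (TSV + per-class FASTA + manifest);
#'   `NULL` skips writing.
#' @inheritParams run_design_campaign
#' @param ... Passed to [run_design_campaign()].
#' @return The candidate `data.frame`.
#' @export
run_design_pipeline <- function(train_records, test_sequences, model,
                                n_high_seeds = 3000L, n_low_seeds = 3000L,
                                n_high = 1500L, n_low = 1500L,
                                constraints = diversity_constraints(),
                                rng_seed = 1L, out_dir = NULL, ...) {
  cand <- run_design_campaign(train_records, test_sequences, model,
                              n_high_seeds = n_high_seeds,
                              n_low_seeds = n_low_seeds,
                              n_high = n_high, n_low = n_low,
                              constraints = constraints,
                              rng_seed = rng_seed, ...)
  ord <- order(-train_records$intensity, train_records$id)
  refs <- list(high = train_records$sequence[ord[seq_len(n_high_seeds)]],
               low = train_records$sequence[rev(ord)[seq_len(n_low_seeds)]],
               test = test_sequences)
  violations <- verify_design_constraints(cand, refs, constraints)
  if (violations > 0L) {
    stop(violations, " candidate(s) violate diversity constraints; walker bug")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peptide_table(cand, file.path(out_dir, "design_candidates.tsv"),
                        comment = c("design candidates: probability is the ensemble posterior",
                                    sprintf("constraints: kmer=%d window=%d max_identities=%d",
                                            constraints$kmer, constraints$window,
                                            constraints$max_identities)))
    for (cl in c("H", "M", "L")) {
      sub <- cand[cand$class == cl, , drop = FALSE]
      if (nrow(sub)) write_fasta(sub, file.path(out_dir, paste0("class_", cl, ".fasta")))
    }
    write_manifest(file.path(out_dir, "manifest.json"), "design",
                   list(rng_seed = rng_seed, n_high_seeds = n_high_seeds,
                        n_low_seeds = n_low_seeds, n_high = n_high,
                        n_low = n_low, constraints = unclass(constraints)),
                   outputs = file.path(out_dir, "design_candidates.tsv"))
  }
  cand
}

#' Evaluation pipeline stage
#'
#' Computes the full metric suite for a set of predictions with measured
#' intensities: the grey-zone curve over a delta grid, the permutation F1
#' p-value, the diversity profile of the predicted classes, and the
#' positional propensity matrix of true-positive H designs against the
#' measured-low set.
#'
#' @param candidates Candidate `data.frame` with `sequence`, `class`.
#' @param intensities Measured intensities aligned to `candidates`.
#' @param center Grey-zone center (default 5500).
#' @param deltas Delta grid.
#' @param B Label permutations for the F1 test.
#' @param cutoffs Hamming cutoffs for the diversity profile.
#' @param rng_seed Integer seed.
#' @param out_dir Output directory for TSVs; `NULL` skips writing.
#' @return List: `delta_curve`, `permutation`, `diversity`, `propensity`.
#' @export
run_evaluation_pipeline <- function(candidates, intensities, center = 5500,
                                    deltas = seq(0, 4500, length.out = 50),
                                    B = 1000L, cutoffs = 1:15,
                                    rng_seed = 1L, out_dir = NULL) {
  hl <- candidates$class %in% c("H", "L")
  pred <- candidates$class[hl]
  meas <- intensities[hl]
  curve <- delta_metrics_curve(meas, pred, center, deltas)
  perm <- permutation_f1_pvalue(pred, meas > center, B = B,
                                rng_seed = rng_seed)
  div <- diversity_profile(candidates$sequence[hl], cutoffs)
  tp_high <- candidates$sequence[hl][pred == "H" & meas > center]
  measured_low <- candidates$sequence[hl][meas <= center]
  prop <- if (length(tp_high) && length(measured_low)) {
    propensity_matrix(tp_high, measured_low)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(curve, file.path(out_dir, "delta_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(div, file.path(out_dir, "diversity_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(prop)) {
      utils::write.table(data.frame(position = rownames(prop),
                                    unclass(prop), check.names = FALSE),
                         file.path(out_dir, "propensity_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(file.path(out_dir, "manifest.json"), "evaluate",
                   list(center = center, B = B, rng_seed = rng_seed,
                        p_value = perm$p_value,
                        observed_f1 = perm$observed_f1))
  }
  list(delta_curve = curve, permutation = perm, diversity = div,
       propensity = prop)
}
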