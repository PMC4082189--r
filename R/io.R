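# Plain-text persistence: cohorts as per-subject CSV files plus a JSON
# manifest, evidence matrices and experiment summaries as CSV, configs and
# EM diagnostics as JSON.

#' Write a cohort to a directory of CSV files
#'
#' Layout: `manifest.json` (tr, seed, true model ids, masks, noise level,
#' node labels), `subject<i>_bold.csv` and, when present,
#' `subject<i>_inputs.csv` at the fine input resolution.
#'
#' @param cohort a `dcm_cohort`.
#' @param path output directory (created if needed).
#' @param inputs also write the fine-resolution input series (large).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, inputs = TRUE) {
  stopifnot(inherits(cohort, "dcm_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_subjects = cohort$n_subjects, tr = cohort$tr,
                   seed = cohort$seed, true_model_id = cohort$true_model_id,
                   noise_sd_frac = cohort$noise_sd_frac,
                   node_labels = cohort$node_labels,
                   missing_mask = cohort$missing_mask,
                   dt = cohort$subjects[[1]]$dt,
                   fill_method = cohort$fill_method %||% NA)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_len(cohort$n_subjects)) {
    s <- cohort$subjects[[i]]
    data.table::fwrite(data.table::as.data.table(s$bold),
                       file.path(path, sprintf("subject%03d_bold.csv", i)))
    if (inputs && !is.null(s$inputs))
      data.table::fwrite(data.table::as.data.table(as.matrix(s$inputs)),
                         file.path(path, sprintf("subject%03d_inputs.csv", i)))
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path directory containing `manifest.json`.
#' @return a `dcm_cohort` (without the simulation ground truth).
#' @export
read_cohort <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- lapply(seq_len(manifest$n_subjects), function(i) {
    bold <- as.matrix(data.table::fread(
      file.path(path, sprintf("subject%03d_bold.csv", i))))
    ifile <- file.path(path, sprintf("subject%03d_inputs.csv", i))
    inputs <- if (file.exists(ifile)) as.matrix(data.table::fread(ifile)) else NULL
    node_time_series(bold, tr = manifest$tr, inputs = inputs,
                     dt = manifest$dt, node_labels = manifest$node_labels)
  })
  mask <- manifest$missing_mask
  if (is.matrix(mask)) mask <- lapply(seq_len(nrow(mask)), function(i) mask[i, ])
  structure(list(subjects = subjects,
                 true_model_id = manifest$true_model_id,
                 missing_mask = mask, truth = NULL, seed = manifest$seed,
                 tr = manifest$tr, noise_sd_frac = manifest$noise_sd_frac,
                 node_labels = manifest$node_labels,
                 n_subjects = manifest$n_subjects,
                 fill_method = manifest$fill_method),
            class = "dcm_cohort")
}

#' Write an evidence matrix to CSV
#'
#' One row per subject, one `model_<id>` column per model, plus subject id
#' and fill tag.
#'
#' @param ev an [evidence_matrix()].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_evidence <- function(ev, file) {
  stopifnot(inherits(ev, "evidence_matrix"))
  dt <- data.table::data.table(subject = ev$subject_ids,
                               fill = ev$fill_method)
  for (j in seq_along(ev$model_ids))
    dt[[sprintf("model_%d", ev$model_ids[j])]] <- ev$log_evidence[, j]
  data.table::fwrite(dt, file)
  invisible(file)
}

#' Read an evidence matrix written by [write_evidence()]
#'
#' @param file CSV path.
#' @return an [evidence_matrix()].
#' @export
read_evidence <- function(file) {
  dt <- data.table::fread(file)
  mcols <- grep("^model_", names(dt), value = TRUE)
  evidence_matrix(as.matrix(dt[, mcols, with = FALSE]),
                  model_ids = as.integer(sub("^model_", "", mcols)),
                  subject_ids = dt$subject,
                  fill_method = dt$fill[1])
}

#' Serialize a model family to JSON
#'
#' Explicit adjacency lists so experiments are reproducible from the file.
#'
#' @param family list of [candidate_model()].
#' @param file output JSON path.
#' @return `file`, invisibly.
#' @export
write_family <- function(family, file) {
  out <- lapply(family, function(m)
    list(model_id = m$model_id, node_labels = m$node_labels,
         topology = m$topology, input_map = m$input_map,
         modulation = m$modulation))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a model family from JSON
#'
#' @param file path written by [write_family()].
#' @return list of [candidate_model()].
#' @export
read_family <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fam <- lapply(raw, function(m)
    candidate_model(m$model_id,
                    matrix(unlist(m$topology), 4, 4, byrow = FALSE),
                    node_labels = unlist(m$node_labels),
                    input_map = unlist(m$input_map),
                    modulation = lapply(m$modulation, function(mo)
                      list(input = as.integer(mo$input), from = mo$from,
                           to = mo$to))))
  keys <- vapply(fam, function(m) paste(m$topology, collapse = ""), character(1))
  if (anyDuplicated(keys)) stop("model family file contains duplicate topologies")
  fam
}

#' Write EM diagnostics to JSON
#'
#' @param fit a `gaussian_estimate` from [em_fit_gaussian()].
#' @param file output JSON path.
#' @return `file`, invisibly.
#' @export
write_em_diagnostics <- function(fit, file) {
  stopifnot(inherits(fit, "gaussian_estimate"))
  jsonlite::write_json(list(mean = fit$mean, cov = fit$cov,
                            loglik_trace = fit$loglik_trace,
                            n_iter = fit$n_iter, converged = fit$converged,
                            mask = fit$mask),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
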