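# End-to-end orchestration: simulate -> collapse -> similarity ->
# persistence -> classify -> report.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_logo_tsv <- function(logo, path) {
  df <- tibble::as_tibble(logo, rownames = "aa")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Run the full repertoire drift analysis pipeline
#'
#' Simulates (or loads) a longitudinal repertoire study and runs every
#' analysis stage: writing the annotated rearrangement tables and FASTA,
#' collapsing clonotypes per subject and timepoint, pairwise Morisita-Horn
#' similarity of all biological replicates with single-linkage clustering,
#' stratified intra- versus inter-timepoint similarity, sequence- and
#' clonotype-level persistence with sharing-versus-depth curves, shared
#' versus unshared clonotype characterization, persistent public clonotype
#' analysis, and leave-one-replicate-out classification. All outputs are
#' written as TSV under `out_dir` together with a JSON run manifest (package
#' version, seed, configuration hash, per-stage record counts). Reruns with
#' the same configuration reproduce the outputs exactly.
#'
#' @param config A [sim_config()]; its seed drives all randomness, with
#'   per-stage seeds derived deterministically from it.
#' @param out_dir Output directory (created if needed).
#' @param records Optional pre-loaded record tibble; if supplied, the
#'   simulation stage is skipped and `config` is used only for seeds.
#' @param depths Depth grid for sharing-versus-depth curves.
#' @param n_boot Bootstrap resamples per depth.
#' @param size_grid,n_repeats Classification evaluation grid.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         records = NULL,
                         depths = c(10, 100, 1000),
                         n_boot = 20,
                         size_grid = c(10, 100, 500),
                         n_repeats = 2) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "repdrift",
    version = as.character(utils::packageVersion("repdrift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(jsonlite::serializeJSON(unclass(config))),
    counts = list()
  )

  truth <- NULL
  if (is.null(records)) {
    sim <- .stage("simulate", simulate_study(config))
    records <- sim$records
    truth <- sim$truth
    .stage("write", {
      write_rearrangements(records, file.path(out_dir, "rearrangements.tsv"))
      write_ground_truth(truth, file.path(out_dir, "ground_truth.tsv"))
      export_fasta(records, file.path(out_dir, "rearrangements.fasta"))
    })
  }
  manifest$counts$records <- nrow(records)

  subjects <- sort(unique(records$subject))
  timepoints <- sort(unique(records$timepoint))

  tables <- .stage("collapse", {
    tabs <- list()
    for (s in subjects) for (tp in timepoints) {
      sub <- records[records$subject == s & records$timepoint == tp, ,
                     drop = FALSE]
      if (nrow(sub) == 0) next
      tab <- collapse_clonotypes(sub)
      write_clonotypes(tab, file.path(out_dir,
                                      sprintf("clonotypes_%s_%s.tsv", s, tp)))
      tabs[[paste(s, tp, sep = "_")]] <- tab
    }
    tabs
  })
  manifest$counts$clonotype_tables <- vapply(tables, nrow, integer(1))

  sim_res <- .stage("similarity", {
    samples <- split_replicates(records)
    mat <- pairwise_similarity(samples)
    readr::write_tsv(tibble::as_tibble(mat, rownames = "sample"),
                     file.path(out_dir, "similarity_matrix.tsv"),
                     progress = FALSE)
    tree <- cluster_replicates(mat)
    writeLines(tree$labels[tree$order],
               file.path(out_dir, "cluster_leaf_order.txt"))
    strat <- stratified_similarity(records)
    readr::write_tsv(strat, file.path(out_dir, "stratified_similarity.tsv"),
                     progress = FALSE)
    list(matrix = mat, tree = tree, stratified = strat)
  })

  pers_res <- .stage("persistence", {
    reports <- list()
    curves <- list()
    chars <- list()
    for (i in seq_along(subjects)) {
      s <- subjects[i]
      if (length(timepoints) < 2) break
      r1 <- records[records$subject == s &
                      records$timepoint == timepoints[1], , drop = FALSE]
      r2 <- records[records$subject == s &
                      records$timepoint == timepoints[2], , drop = FALSE]
      for (lev in c("clonotype", "sequence")) {
        reports[[paste(s, lev, sep = "_")]] <-
          dplyr::mutate(persistence_report(r1, r2, level = lev),
                        subject = s, .before = 1)
      }
      curves[[s]] <- dplyr::mutate(
        sharing_vs_depth(r1, r2, depths = depths, n_boot = n_boot,
                         seed = derive_seed(config$seed, i)),
        subject = s, .before = 1)
      chars[[s]] <- characterize_persistent(r1, r2)
      readr::write_tsv(chars[[s]]$tests,
                       file.path(out_dir,
                                 sprintf("persistent_tests_%s.tsv", s)),
                       progress = FALSE)
      for (gr in names(chars[[s]]$logos)) {
        if (!is.null(chars[[s]]$logos[[gr]])) {
          write_logo_tsv(chars[[s]]$logos[[gr]],
                         file.path(out_dir,
                                   sprintf("logo_%s_%s.tsv", s, gr)))
        }
      }
    }
    if (length(reports)) {
      readr::write_tsv(dplyr::bind_rows(reports),
                       file.path(out_dir, "persistence_reports.tsv"),
                       progress = FALSE)
    }
    if (length(curves)) {
      readr::write_tsv(dplyr::bind_rows(curves),
                       file.path(out_dir, "sharing_vs_depth.tsv"),
                       progress = FALSE)
    }
    list(reports = reports, curves = curves, characterization = chars)
  })

  pp_res <- NULL
  if (length(subjects) >= 2 && length(timepoints) >= 2) {
    pp_res <- .stage("persistent_public", {
      pp <- persistent_public(records)
      readr::write_tsv(pp$lengths,
                       file.path(out_dir, "persistent_public_lengths.tsv"),
                       progress = FALSE)
      writeLines(pp$persistent_public,
                 file.path(out_dir, "persistent_public_keys.txt"))
      pp
    })
    manifest$counts$public <- length(pp_res$public)
    manifest$counts$persistent_public <- length(pp_res$persistent_public)
  }

  cls_res <- NULL
  if (length(subjects) * length(timepoints) >= 2) {
    cls_res <- .stage("classify", {
      ev <- evaluate_loro(records, size_grid = size_grid,
                          n_repeats = n_repeats,
                          seed = derive_seed(config$seed, 99))
      readr::write_tsv(ev$summary, file.path(out_dir, "classification_auc.tsv"),
                       progress = FALSE)
      ev
    })
  }

  manifest$outputs <- sort(list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    records = records, truth = truth, clonotype_tables = tables,
    similarity = sim_res, persistence = pers_res,
    persistent_public = pp_res, classification = cls_res,
    manifest = manifest
  ))
}
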