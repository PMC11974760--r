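# One-versus-rest SVM classification of replicate repertoires by subject and
# timepoint, from V-gene / J-gene / CDRH3-length frequency features, with
# leave-one-replicate-out evaluation.

#' Build a feature vocabulary
#'
#' Fixes the feature space for [featurize()]: the V genes and J genes to
#' track (each block gets an `OTHER` bucket for genes outside the
#' vocabulary) and the CDRH3 length range (default 5-35 amino acids, with an
#' `OTHER` bucket for lengths outside it).
#'
#' @param records Optional record tibble from which to take the observed
#'   gene sets.
#' @param v_genes,j_genes Explicit gene sets (override `records`).
#' @param lengths Integer CDRH3 length range.
#' @return A list with elements `v_genes`, `j_genes`, `lengths`.
#' @export
feature_vocabulary <- function(records = NULL, v_genes = NULL,
                               j_genes = NULL, lengths = 5:35) {
  if (is.null(v_genes)) {
    if (is.null(records)) stop("need records or explicit gene sets",
                               call. = FALSE)
    v_genes <- sort(unique(records$v_gene))
  }
  if (is.null(j_genes)) {
    if (is.null(records)) stop("need records or explicit gene sets",
                               call. = FALSE)
    j_genes <- sort(unique(records$j_gene))
  }
  list(v_genes = v_genes, j_genes = j_genes, lengths = as.integer(lengths))
}

.block_freq <- function(values, levels) {
  f <- factor(ifelse(values %in% levels, as.character(values), "OTHER"),
              levels = c(as.character(levels), "OTHER"))
  tab <- as.numeric(table(f))
  tab / length(values)
}

.featurize_sample <- function(records, vocabulary, n_sequences = NULL,
                              replace = FALSE) {
  idx <- seq_len(nrow(records))
  if (!is.null(n_sequences)) {
    if (n_sequences > nrow(records) && !replace) {
      stop("n_sequences exceeds available records; set replace = TRUE",
           call. = FALSE)
    }
    idx <- sample.int(nrow(records), n_sequences, replace = replace)
  }
  sub <- records[idx, , drop = FALSE]
  v <- .block_freq(sub$v_gene, vocabulary$v_genes)
  j <- .block_freq(sub$j_gene, vocabulary$j_genes)
  l <- .block_freq(sub$cdrh3_length, vocabulary$lengths)
  x <- c(v, j, l)
  names(x) <- c(paste0("V:", c(vocabulary$v_genes, "OTHER")),
                paste0("J:", c(vocabulary$j_genes, "OTHER")),
                paste0("L:", c(vocabulary$lengths, "OTHER")))
  list(x = x, ids = sub$sequence_id)
}

#' Featurize a repertoire sample
#'
#' Computes the concatenation of three normalized frequency blocks — V-gene
#' usage, J-gene usage and CDRH3 length distribution — from a (sub)sample of
#' records. Genes or lengths outside the vocabulary are pooled into an
#' `OTHER` bucket. Each block sums to 1.
#'
#' @param records Record tibble.
#' @param vocabulary From [feature_vocabulary()].
#' @param n_sequences If given, compute frequencies from a random subsample
#'   of this many records (seed the session for reproducibility).
#' @param replace Allow sampling with replacement (required when
#'   `n_sequences` exceeds the census).
#' @return Named numeric feature vector.
#' @export
featurize <- function(records, vocabulary, n_sequences = NULL,
                      replace = FALSE) {
  .featurize_sample(records, vocabulary, n_sequences, replace)$x
}

.svm_ovr_scores <- function(train_x, train_y, test_x, cost = 1) {
  classes <- sort(unique(train_y))
  scores <- matrix(NA_real_, nrow = nrow(test_x), ncol = length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    y <- factor(ifelse(train_y == cl, "pos", "rest"),
                levels = c("pos", "rest"))
    fit <- e1071::svm(train_x, y, kernel = "linear", cost = cost,
                      scale = FALSE)
    pr <- predict(fit, test_x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients the decision value toward the class named first in the
    # column label, which follows training-data order
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    scores[, cl] <- if (first == "pos") dv[, 1] else -dv[, 1]
  }
  scores
}

.auc <- function(labels, scores) {
  r <- pROC::roc(response = factor(labels, levels = c(FALSE, TRUE)),
                 predictor = scores, direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Leave-one-replicate-out classification of repertoires
#'
#' Evaluates how well replicate repertoires can be assigned to their
#' (subject, timepoint) class from V-gene, J-gene and CDRH3-length frequency
#' features alone. For every rotation, one biological replicate per class is
#' held out; a linear-kernel one-versus-rest support-vector machine
#' (regularization constant `cost`) is trained on feature vectors drawn from
#' the remaining replicates and scores the held-out replicates. A
#' one-versus-rest ROC AUC is computed per class within each rotation
#' (decision scores from different fits live on different scales and are
#' never pooled) and averaged over rotations; this is repeated `n_repeats`
#' times per training/test size.
#' Held-out records never contribute to training features; the returned
#' audit counts sequence-id overlap between the train and test draws of
#' every rotation (zero by construction).
#'
#' @param records Record tibble covering at least 2 (subject, timepoint)
#'   classes with the same number (>= 2) of biological replicates each.
#' @param size_grid Training/test sample sizes (sequences per feature
#'   vector).
#' @param n_repeats Independent repetitions per size.
#' @param n_draws Feature vectors drawn per training replicate.
#' @param seed Optional seed.
#' @param cost SVM regularization constant.
#' @param vocabulary Optional [feature_vocabulary()]; default is built from
#'   `records`.
#' @return A list: `auc` (tibble `size`, `rep`, `class`, `auc`), `summary`
#'   (mean AUC per size and class), `audit` (tibble with `n_leaked` per
#'   size/repeat/rotation).
#' @export
evaluate_loro <- function(records, size_grid = c(10, 50, 100, 500, 1000,
                                                 5000),
                          n_repeats = 3, n_draws = 3, seed = NULL, cost = 1,
                          vocabulary = NULL) {
  records$.class <- paste(records$subject, records$timepoint, sep = "_")
  classes <- sort(unique(records$.class))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  by_class <- split(records, records$.class)
  reps_per_class <- lapply(by_class, function(s) sort(unique(s$replicate)))
  n_reps <- unique(vapply(reps_per_class, length, integer(1)))
  if (length(n_reps) != 1 || n_reps < 2) {
    stop("every class needs the same number (>= 2) of biological replicates",
         call. = FALSE)
  }
  if (is.null(vocabulary)) vocabulary <- feature_vocabulary(records)

  run <- function() {
    auc_rows <- list()
    audit_rows <- list()
    for (size in size_grid) {
      for (rp in seq_len(n_repeats)) {
        labels <- list()
        scores <- list()
        for (rot in seq_len(n_reps)) {
          train_x <- list(); train_y <- character(0)
          test_x <- list(); test_y <- character(0)
          train_ids <- character(0); test_ids <- character(0)
          for (cl in classes) {
            crecs <- by_class[[cl]]
            reps <- reps_per_class[[cl]]
            held <- reps[rot]
            for (rlab in reps) {
              rrecs <- crecs[crecs$replicate == rlab, , drop = FALSE]
              if (rlab == held) {
                fs <- .featurize_sample(rrecs, vocabulary, size,
                                        replace = TRUE)
                test_x[[length(test_x) + 1L]] <- fs$x
                test_y <- c(test_y, cl)
                test_ids <- c(test_ids, fs$ids)
              } else {
                for (dd in seq_len(n_draws)) {
                  fs <- .featurize_sample(rrecs, vocabulary, size,
                                          replace = TRUE)
                  train_x[[length(train_x) + 1L]] <- fs$x
                  train_y <- c(train_y, cl)
                  train_ids <- c(train_ids, fs$ids)
                }
              }
            }
          }
          sc <- .svm_ovr_scores(do.call(rbind, train_x), train_y,
                                do.call(rbind, test_x), cost = cost)
          # one ROC per rotation and class: decision scores from different
          # fits are not on a common scale, so they are never pooled
          labels[[rot]] <- test_y
          scores[[rot]] <- sc
          audit_rows[[length(audit_rows) + 1L]] <- tibble::tibble(
            size = size, rep = rp, rotation = rot,
            n_leaked = length(intersect(unique(train_ids),
                                        unique(test_ids)))
          )
        }
        for (cl in classes) {
          per_rot <- vapply(seq_len(n_reps), function(rot) {
            .auc(labels[[rot]] == cl, scores[[rot]][, cl])
          }, numeric(1))
          auc_rows[[length(auc_rows) + 1L]] <- tibble::tibble(
            size = size, rep = rp, class = cl, auc = mean(per_rot)
          )
        }
      }
    }
    list(auc = dplyr::bind_rows(auc_rows),
         audit = dplyr::bind_rows(audit_rows))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  res$summary <- dplyr::summarise(
    dplyr::group_by(res$auc, .data$size, .data$class),
    mean_auc = mean(.data$auc), .groups = "drop"
  )
  res[c("auc", "summary", "audit")]
}
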