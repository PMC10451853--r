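## F1 scoring, confusion matrices and the experiment harnesses:
## directed cross-collection validation, joined-data training, and the
## hybrid-class comparison.

#' Per-class F1 score from margin counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall.
#' Returns 0 when the denominator is 0 (no true or predicted positives).
#'
#' @param tp,fp,fn non-negative counts (vectorized).
#' @return F1 in \[0, 1\].
#' @export
#' @examples
#' f1_score(2, 1, 0)  # 0.8
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, 0, 2 * tp / denom)
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param true,pred parallel label vectors.
#' @param classes class label order (default: sorted union).
#' @return K x K integer matrix with dimnames.
#' @export
confusion <- function(true, pred, classes = sort(unique(c(true, pred)))) {
  if (length(true) != length(pred))
    stop("true and pred must have equal length")
  bad <- setdiff(unique(c(true, pred)), classes)
  if (length(bad) > 0)
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  tt <- factor(true, levels = classes)
  pp <- factor(pred, levels = classes)
  as.matrix(table(true = tt, predicted = pp))
}

#' Row-normalize a confusion matrix
#'
#' Each nonempty row is divided by its sum (per-true-class rates); empty rows
#' stay zero.
#'
#' @param cm confusion matrix (rows = true classes).
#' @return numeric matrix with rows summing to 1 (or 0).
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  sweep(cm, 1, ifelse(rs == 0, 1, rs), "/")
}

#' Per-class precision/recall/F1 from a confusion matrix
#'
#' @param cm K x K confusion matrix (rows true, columns predicted).
#' @return data.frame with class, tp, fp, fn, precision, recall, f1.
#' @export
f1_from_confusion <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  data.frame(class = colnames(cm), tp = tp, fp = fp, fn = fn,
             precision = ifelse(tp + fp == 0, 0, tp / (tp + fp)),
             recall = ifelse(tp + fn == 0, 0, tp / (tp + fn)),
             f1 = f1_score(tp, fp, fn),
             row.names = NULL, stringsAsFactors = FALSE)
}

## ---- task label mapping -----------------------------------------------------

task_labels <- function(labels, task, species_set = c("P_pip", "P_nat", "P_pyg"),
                        with_hybrids = FALSE) {
  if (task == "batnoise") {
    ifelse(labels == "noise", "noise", "bat")
  } else if (task == "genus") {
    out <- map_to_genus(labels)
    out[out == "excluded"] <- NA_character_
    out
  } else if (task == "species") {
    keep <- if (with_hybrids) c(species_set, "P_low", "P_high") else species_set
    ifelse(labels %in% keep, labels, NA_character_)
  } else stop("unknown task: ", task)
}

# Segment a named list of recordings, compute MFCCs and task labels, assign a
# recording-level stratified split. feature_args tunes the analysis setting
# (e.g. reduced-resolution MFCCs for quick experiments).
prepare_task_data <- function(recordings, task, ratios = c(0.6, 0.2, 0.2),
                              seed = 1L, feature_args = list(),
                              with_hybrids = FALSE, sf = NULL) {
  if (is.null(sf))
    sf <- do.call(segment_features,
                  c(list(recordings = recordings, type = "mfcc"), feature_args))
  lab <- task_labels(sf$labels, task, with_hybrids = with_hybrids)
  keep <- !is.na(lab)
  feats <- sf$features[keep]
  lab <- lab[keep]
  rid <- sf$recording_id[keep]
  rec_tab <- data.frame(file = unique(rid),
                        class = lab[match(unique(rid), rid)],
                        stringsAsFactors = FALSE)
  split_tab <- suppressWarnings(
    stratified_split(rec_tab, ratios = ratios, seed = seed))
  split <- split_tab$split[match(rid, split_tab$file)]
  list(features = feats, labels = lab, recording_id = rid, split = split)
}

run_f1_matrix <- function(runs, feats, labels, classes) {
  if (length(feats) == 0) {
    warning("empty partition: F1 reported as NA")
    return(matrix(NA_real_, length(runs), length(classes),
                  dimnames = list(NULL, classes)))
  }
  t(vapply(runs, function(r) {
    pred <- clf_predict(r$model, feats)$labels
    cm <- confusion(labels, pred, classes)
    stats::setNames(f1_from_confusion(cm)$f1, classes)
  }, numeric(length(classes))))
}

mean_sd_report <- function(f1_by_partition, classes) {
  do.call(rbind, lapply(names(f1_by_partition), function(p) {
    m <- f1_by_partition[[p]]
    data.frame(partition = p, class = classes,
               f1_mean = apply(m, 2, mean), f1_sd = apply(m, 2, stats::sd),
               n_runs = nrow(m), row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Directed collection pairs sharing a year or a location
#'
#' Collection ids are `location_year` tags (e.g. `"east_2019"`). The
#' cross-validation design evaluates every ordered pair that shares the year
#' or the location: for 2 locations x 2 years this yields 8 directed pairs.
#'
#' @param ids character vector of collection ids.
#' @return data.frame with columns `train`, `test`.
#' @export
collection_pairs <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  loc <- vapply(parts, `[`, "", 1)
  yr <- vapply(parts, `[`, "", 2)
  out <- expand.grid(train = ids, test = ids, stringsAsFactors = FALSE)
  out <- out[out$train != out$test, ]
  i <- match(out$train, ids); j <- match(out$test, ids)
  out <- out[loc[i] == loc[j] | yr[i] == yr[j], ]
  rownames(out) <- NULL
  out
}

#' Directed cross-collection validation
#'
#' For each directed pair of collections (A -> B) sharing a year or location,
#' trains on A's training partition, monitors A's validation partition and
#' tests on B's test partition, repeating over `config$runs` seeded runs.
#' Per-class F1 is pooled over all pairs and runs (mean and standard
#' deviation), the averaged cross-validation protocol.
#'
#' @param collections named list: collection id -> list of `bat_recording`s.
#' @param task `"batnoise"`, `"genus"` or `"species"`.
#' @param config a [clf_config()].
#' @param ratios split proportions.
#' @param seed split seed.
#' @param feature_args list of arguments for [compute_mfcc()] (e.g. reduced
#'   resolution settings for quick experiments).
#' @return list with `pairs` (the directed design), `per_pair` (per-pair
#'   reports) and `summary` (per class x partition pooled mean +/- sd).
#' @export
cross_collection_eval <- function(collections, task, config = clf_config(task),
                                  ratios = c(0.6, 0.2, 0.2), seed = 1L,
                                  feature_args = list()) {
  if (length(collections) < 2) stop("need at least 2 collections")
  prep <- lapply(collections, prepare_task_data, task = task, ratios = ratios,
                 seed = seed, feature_args = feature_args)
  class_sets <- lapply(prep, function(p) sort(unique(p$labels)))
  classes <- sort(Reduce(intersect, class_sets))
  if (length(classes) < 2)
    stop("fewer than 2 classes shared by all collections")
  dropped <- setdiff(sort(unique(unlist(class_sets))), classes)
  if (length(dropped) > 0)
    warning("class(es) not present in every collection, skipped: ",
            paste(dropped, collapse = ", "))
  pairs <- collection_pairs(names(collections))
  acc <- list(train = NULL, val = NULL, test = NULL)
  per_pair <- list()
  for (p in seq_len(nrow(pairs))) {
    A <- prep[[pairs$train[p]]]; B <- prep[[pairs$test[p]]]
    tr <- A$split == "train" & A$labels %in% classes
    va <- A$split == "val" & A$labels %in% classes
    te <- B$split == "test" & B$labels %in% classes
    runs <- train_classifier_runs(A$features[tr], A$labels[tr],
                                  classes = classes, config = config,
                                  balance = (task == "batnoise"))
    f1s <- list(
      train = run_f1_matrix(runs, A$features[tr], A$labels[tr], classes),
      val = run_f1_matrix(runs, A$features[va], A$labels[va], classes),
      test = run_f1_matrix(runs, B$features[te], B$labels[te], classes))
    per_pair[[paste(pairs$train[p], "->", pairs$test[p])]] <-
      mean_sd_report(f1s, classes)
    for (part in names(acc)) acc[[part]] <- rbind(acc[[part]], f1s[[part]])
  }
  list(pairs = pairs, per_pair = per_pair,
       summary = mean_sd_report(acc, classes), classes = classes)
}

#' Joined-data training and evaluation
#'
#' Joins all collections into one dataset, splits 60:20:20 with per-class
#' stratification (preserving the natural imbalance), trains `config$runs`
#' models and reports per-class F1 (mean +/- sd) on train, validation and
#' test partitions. Agreement of validation and test F1 within the run
#' spread is the robustness signature of a model that has comprehended the
#' feature space.
#'
#' @inheritParams cross_collection_eval
#' @param with_hybrids include the hybrid classes in the species task.
#' @param .sf advanced: a precomputed [segment_features()] result; skips
#'   segmentation/feature extraction (and the `collections` argument).
#' @return list with `report` (summary data.frame), `runs_f1` (per-partition
#'   run x class F1 matrices), `models`, `classes`, and `confusion` (mean
#'   test-partition confusion matrix over runs, absolute counts).
#' @export
joined_eval <- function(collections, task, config = clf_config(task),
                        ratios = c(0.6, 0.2, 0.2), seed = 1L,
                        feature_args = list(), with_hybrids = FALSE,
                        .sf = NULL) {
  recs <- if (!is.null(.sf)) NULL
  else if (is.list(collections[[1]]) &&
           inherits(collections[[1]][[1]], "bat_recording"))
    unlist(collections, recursive = FALSE) else collections
  prep <- prepare_task_data(recs, task, ratios = ratios, seed = seed,
                            feature_args = feature_args,
                            with_hybrids = with_hybrids, sf = .sf)
  classes <- sort(unique(prep$labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  sel <- list(train = prep$split == "train", val = prep$split == "val",
              test = prep$split == "test")
  runs <- train_classifier_runs(prep$features[sel$train],
                                prep$labels[sel$train], classes = classes,
                                config = config,
                                balance = (task == "batnoise"))
  f1s <- lapply(sel, function(ix)
    run_f1_matrix(runs, prep$features[ix], prep$labels[ix], classes))
  cms <- lapply(runs, function(r) {
    pred <- clf_predict(r$model, prep$features[sel$test])$labels
    confusion(prep$labels[sel$test], pred, classes)
  })
  cm_mean <- Reduce(`+`, cms) / length(cms)
  list(report = mean_sd_report(f1s, classes), runs_f1 = f1s, models = runs,
       classes = classes, confusion = cm_mean)
}

#' Hybrid-class comparison experiment
#'
#' Trains two species classifiers on the same joined data: one without and
#' one with the hybrid class `P_low` (calls in the 40-42 kHz band shared by
#' *P. pipistrellus* and *P. nathusii*). Returns both reports plus the mean
#' test confusion matrices (absolute and row-normalized) and the
#' bidirectional confusion mass between `P_low` and its parent species.
#'
#' @inheritParams joined_eval
#' @param .sf advanced: a precomputed [segment_features()] result.
#' @return list with `without`, `with` (both [joined_eval()] results),
#'   `confusion_normalized` (for the with-hybrid model) and `hybrid_mass`
#'   (named counts: P_pip->P_low, P_low->P_pip, P_nat->P_low, P_low->P_nat).
#' @export
hybrid_class_experiment <- function(collections, config = clf_config("species"),
                                    ratios = c(0.6, 0.2, 0.2), seed = 1L,
                                    feature_args = list(), .sf = NULL) {
  if (is.null(.sf)) {
    recs <- if (is.list(collections[[1]]) &&
                inherits(collections[[1]][[1]], "bat_recording"))
      unlist(collections, recursive = FALSE) else collections
    labs <- vapply(recs, function(r) r$meta$class_label %||% NA_character_, "")
    if (!"P_low" %in% labs)
      stop("hybrid experiment requires P_low recordings in the data")
    sf <- do.call(segment_features,
                  c(list(recordings = recs, type = "mfcc"), feature_args))
  } else {
    sf <- .sf
    if (!"P_low" %in% sf$labels)
      stop("hybrid experiment requires P_low recordings in the data")
  }
  without <- joined_eval(NULL, "species", config = config, ratios = ratios,
                         seed = seed, with_hybrids = FALSE, .sf = sf)
  with_h <- joined_eval(NULL, "species", config = config, ratios = ratios,
                        seed = seed, with_hybrids = TRUE, .sf = sf)
  cm <- with_h$confusion
  gm <- function(a, b)
    if (all(c(a, b) %in% rownames(cm))) cm[a, b] else NA_real_
  mass <- c("P_pip->P_low" = gm("P_pip", "P_low"),
            "P_low->P_pip" = gm("P_low", "P_pip"),
            "P_nat->P_low" = gm("P_nat", "P_low"),
            "P_low->P_nat" = gm("P_low", "P_nat"))
  list(without = without, with = with_h,
       confusion_normalized = normalize_confusion(with_h$confusion),
       hybrid_mass = mass)
}
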