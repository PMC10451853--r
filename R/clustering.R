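## UMAP embedding of autoencoder latents with hyperparameter grid search,
## and the unsupervised experiment runners (noise structure by measurement
## height; genera against noise).
##
## UMAP itself is consumed from the uwot package; this module owns the
## surrounding protocol: latent extraction, the grid over (n_neighbors,
## min_dist), and automated selection by silhouette score on the known
## grouping (visual selection of such plots is common practice; silhouette makes
## the choice reproducible while the embeddings remain exportable for visual
## inspection).

#' UMAP configuration
#'
#' @param n_neighbors neighborhood size (>= 2); small values emphasize local,
#'   large values global structure.
#' @param min_dist minimum distance between embedded points, in \[0, 1).
#' @param seed RNG seed (fixed seed gives reproducible embeddings).
#' @return a `umap_config` list.
#' @export
umap_config <- function(n_neighbors = 15L, min_dist = 0.1, seed = 1L) {
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  if (min_dist < 0 || min_dist >= 1) stop("min_dist must be in [0, 1)")
  structure(list(n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 seed = as.integer(seed)),
            class = "umap_config")
}

#' Embed latent vectors in 2-D with UMAP
#'
#' @param latents numeric matrix, one row per sample (flattened latent
#'   feature vectors, or any feature matrix).
#' @param config a [umap_config()].
#' @return n x 2 coordinate matrix.
#' @export
embed_latents <- function(latents, config = umap_config()) {
  latents <- as.matrix(latents)
  if (nrow(latents) < config$n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", config$n_neighbors + 1,
         " samples, got ", nrow(latents))
  set.seed(config$seed)
  coords <- uwot::umap(latents, n_neighbors = config$n_neighbors,
                       min_dist = config$min_dist, n_components = 2,
                       n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  unname(coords)
}

#' Silhouette score of an embedding under known group labels
#'
#' Mean silhouette width over all points. Returns `NA` (sentinel) when fewer
#' than two distinct labels are present.
#'
#' @param coords n x 2 embedding coordinates.
#' @param labels group label per point.
#' @return mean silhouette width in \[-1, 1\], or `NA`.
#' @export
silhouette_score <- function(coords, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Grid search over UMAP hyperparameters
#'
#' Evaluates every (n_neighbors, min_dist) cell, scoring the embedding by
#' silhouette on the known grouping. Cells whose n_neighbors exceeds the
#' sample count are skipped with a warning; if all labels are identical every
#' score is the `NA` sentinel and no best configuration exists. Ties are
#' broken toward smaller n_neighbors, then smaller min_dist.
#'
#' @param latents numeric matrix (rows = samples).
#' @param labels group label per row.
#' @param n_neighbors_grid,min_dist_grid grid values.
#' @param seed seed used for every embedding (same stream per cell).
#' @return list with `results` (data.frame: n_neighbors, min_dist,
#'   silhouette), `best` (row of `results` or NULL), `embeddings` (list of
#'   coordinate matrices, parallel to `results` rows), `labels`.
#' @export
grid_search_umap <- function(latents, labels,
                             n_neighbors_grid = c(5L, 15L, 30L, 50L, 100L),
                             min_dist_grid = c(0, 0.1, 0.25, 0.5),
                             seed = 1L) {
  if (length(n_neighbors_grid) == 0 || length(min_dist_grid) == 0)
    stop("hyperparameter grid must be non-empty")
  latents <- as.matrix(latents)
  grid <- expand.grid(n_neighbors = as.integer(n_neighbors_grid),
                      min_dist = min_dist_grid)
  feasible <- grid$n_neighbors + 1 <= nrow(latents)
  if (!all(feasible))
    warning(sum(!feasible), " grid cell(s) skipped: n_neighbors too large ",
            "for ", nrow(latents), " samples")
  embeddings <- vector("list", nrow(grid))
  scores <- rep(NA_real_, nrow(grid))
  for (i in which(feasible)) {
    cfg <- umap_config(grid$n_neighbors[i], grid$min_dist[i], seed = seed)
    embeddings[[i]] <- embed_latents(latents, cfg)
    scores[i] <- silhouette_score(embeddings[[i]], labels)
  }
  results <- cbind(grid, silhouette = scores)
  best <- NULL
  if (any(!is.na(scores))) {
    ord <- order(-scores, grid$n_neighbors, grid$min_dist, na.last = TRUE)
    best <- results[ord[1], ]
  }
  list(results = results, best = best, embeddings = embeddings,
       labels = as.character(labels))
}

# Draw n_train/n_embed spectrogram indices per group; disjoint when the group
# is large enough, otherwise sampled with replacement (flagged).
draw_group_samples <- function(groups, n_train, n_embed) {
  train_ix <- c(); embed_ix <- c(); flagged <- character(0)
  for (g in sort(unique(groups))) {
    ix <- which(groups == g)
    if (length(ix) >= n_train + n_embed) {
      sh <- sample(ix)
      train_ix <- c(train_ix, sh[seq_len(n_train)])
      embed_ix <- c(embed_ix, sh[n_train + seq_len(n_embed)])
    } else {
      flagged <- c(flagged, g)
      train_ix <- c(train_ix, sample(ix, n_train, replace = TRUE))
      embed_ix <- c(embed_ix, sample(ix, n_embed, replace = TRUE))
    }
  }
  if (length(flagged) > 0)
    warning("group(s) with fewer than n_train + n_embed segments, sampled ",
            "with replacement: ", paste(flagged, collapse = ", "))
  list(train = train_ix, embed = embed_ix)
}

#' Noise clustering by measurement height within a collection
#'
#' The unsupervised protocol for one collection: per measurement height,
#' draw `n_train` random noise spectrograms to train the autoencoder and
#' `n_embed` further spectrograms (disjoint when possible) to embed; encode
#' the embed set, run the UMAP grid search and score height separation by
#' silhouette. Heights without noise segments are omitted with a warning.
#'
#' @param recordings list of `bat_recording`s of one collection (only
#'   recordings labeled `"noise"` are used).
#' @param n_train,n_embed spectrograms per height for autoencoder training
#'   and for embedding.
#' @param ae_cfg an [ae_config()] for autoencoder training.
#' @param seed RNG seed (sampling, model init, UMAP).
#' @param feature_args arguments for [compute_spectrogram()].
#' @param ... grid arguments passed to [grid_search_umap()].
#' @return a [grid_search_umap()] result, plus `heights` (labels of embedded
#'   points) and `model` (the trained autoencoder).
#' @export
run_noise_by_height <- function(recordings, n_train = 250L, n_embed = 250L,
                                ae_cfg = ae_config(), seed = 1L,
                                feature_args = list(), ...) {
  labs <- vapply(recordings, function(r) r$meta$class_label %||% "", "")
  noise_recs <- recordings[labs == "noise"]
  if (length(noise_recs) == 0) stop("no noise recordings in the collection")
  sf <- do.call(segment_features,
                c(list(recordings = noise_recs, type = "spectrogram"),
                  feature_args))
  heights <- sf$height_m
  if (anyNA(heights)) stop("noise recordings must carry height metadata")
  set.seed(seed)
  draw <- draw_group_samples(as.character(heights), n_train, n_embed)
  ae <- build_autoencoder(seed = seed)
  trained <- train_autoencoder(ae, sf$features[draw$train], ae_cfg)
  lat <- t(vapply(draw$embed, function(i)
    latent_vector(encode(trained$model, sf$features[[i]])),
    numeric(length(latent_vector(encode(trained$model, sf$features[[1]]))))))
  res <- grid_search_umap(lat, as.character(heights[draw$embed]),
                          seed = seed, ...)
  res$heights <- heights[draw$embed]
  res$model <- trained$model
  res
}

#' Joined clustering of genera against noise
#'
#' Samples `per_class_n` segments per genus-level class (Nyctaloid, Myotis,
#' Plecotus, Pipistrellus) plus noise, trains the autoencoder on those
#' spectrograms, embeds their latents and grid-searches UMAP, scoring the
#' 5-group separation by silhouette. Missing genera are omitted with a
#' warning; an empty noise set is an error. `per_class_n` outside the
#' 100-500 range used for this protocol triggers a warning.
#'
#' @param recordings list of `bat_recording`s (all collections joined).
#' @param per_class_n segments sampled per class.
#' @inheritParams run_noise_by_height
#' @return a [grid_search_umap()] result plus `groups` and `model`.
#' @export
run_genus_vs_noise <- function(recordings, per_class_n = 100L,
                               ae_cfg = ae_config(), seed = 1L,
                               feature_args = list(), ...) {
  if (per_class_n < 100 || per_class_n > 500)
    warning("per_class_n = ", per_class_n,
            " is outside the protocol's 100-500 range")
  sf <- do.call(segment_features,
                c(list(recordings = recordings, type = "spectrogram"),
                  feature_args))
  grp <- ifelse(sf$labels == "noise", "noise",
                suppressWarnings(map_to_genus(sf$labels)))
  keep <- grp %in% c(genus_labels(), "noise")
  grp <- grp[keep]; feats <- sf$features[keep]
  if (!"noise" %in% grp) stop("no noise segments available")
  missing_gen <- setdiff(genus_labels(), unique(grp))
  if (length(missing_gen) > 0)
    warning("genus class(es) missing, omitted: ",
            paste(missing_gen, collapse = ", "))
  set.seed(seed)
  sel <- unlist(lapply(split(seq_along(grp), grp), function(ix)
    sample(ix, min(per_class_n, length(ix)))))
  ae <- build_autoencoder(seed = seed)
  trained <- train_autoencoder(ae, feats[sel], ae_cfg)
  d <- length(latent_vector(encode(trained$model, feats[[sel[1]]])))
  lat <- t(vapply(sel, function(i)
    latent_vector(encode(trained$model, feats[[i]])), numeric(d)))
  res <- grid_search_umap(lat, grp[sel], seed = seed, ...)
  res$groups <- grp[sel]
  res$model <- trained$model
  res
}
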