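## End-to-end orchestration: configuration validation, the staged pipeline
## (simulate -> preprocess -> autoencoder -> cluster -> classify), caching
## and the run manifest.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "chirpnet_run",
    preprocessing = list(n_fft = 2048L, hop = 512L, n_mfcc = 20L,
                         n_mels = 128L),
    split = c(0.6, 0.2, 0.2),
    autoencoder = list(learning_rate = 1e-4, batch_size = 1L, epochs = 10L,
                       n_train_noise = 250L),
    classifier = list(learning_rate = 1e-4, batch_size = 32L, runs = 5L,
                      epochs = list(batnoise = 10L, genus = 50L,
                                    species = 25L)),
    umap = list(n_neighbors_grid = c(5L, 15L, 30L, 50L, 100L),
                min_dist_grid = c(0, 0.1, 0.25, 0.5)),
    tasks = c("genus"),
    simulate = NULL   # named list: collection id -> collection_config args
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a raw named list or a YAML file path; unknown keys and
#' out-of-range values raise named errors, unset keys take the pipeline
#' defaults (ADAM learning rate 1e-4, autoencoder batch 1 / 10 epochs,
#' classifier batch 32 with task epochs 10/50/25, split 60:20:20).
#'
#' @param raw named list or path to a YAML config file.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a named list or YAML file")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (abs(sum(cfg$split) - 1) > 1e-8)
    stop("config error 'split': ratios must sum to 1")
  if (any(cfg$split < 0)) stop("config error 'split': negative ratio")
  for (f in c("batnoise", "genus", "species"))
    if (cfg$classifier$epochs[[f]] < 1)
      stop("config error 'classifier.epochs.", f, "': epochs must be >= 1")
  if (cfg$autoencoder$epochs < 1)
    stop("config error 'autoencoder.epochs': epochs must be >= 1")
  if (cfg$autoencoder$learning_rate <= 0 || cfg$classifier$learning_rate <= 0)
    stop("config error: learning rates must be positive")
  bad_task <- setdiff(cfg$tasks, c("batnoise", "genus", "species"))
  if (length(bad_task) > 0)
    stop("config error 'tasks': unknown task(s) ",
         paste(bad_task, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

config_digest <- function(cfg) {
  # stable content digest used for stage caching (no external deps)
  s <- paste(utils::capture.output(utils::str(unclass(cfg), digits.d = 12)),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

stage_cached <- function(manifest_path, digest, stage) {
  if (!file.exists(manifest_path)) return(FALSE)
  m <- jsonlite::read_json(manifest_path)
  identical(m$config_digest, digest) && stage %in% unlist(m$stages_done)
}

#' Run the analysis pipeline
#'
#' Executes the staged flow on a synthetic corpus defined by the config:
#' simulate (WAV collections + catalogs), preprocess (feature cache),
#' autoencoder (train on noise spectrograms), cluster (noise-by-height UMAP
#' grid search per collection), classify (joined-data training + F1 reports
#' for the configured tasks). Stages already recorded in the run manifest
#' under an identical config digest are skipped (idempotent reruns). Any
#' stage error halts the run naming the stage.
#'
#' @param config a [validate_config()] result (or raw list/YAML path).
#' @param stages subset of stages to run.
#' @return the run manifest (list), invisibly; written as `manifest.json` in
#'   the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "autoencoder",
                                    "cluster", "classify")) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  if (is.null(cfg$simulate) && "simulate" %in% stages)
    stop("stage 'simulate': config$simulate must define the collections")
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  digest <- config_digest(cfg)
  manifest <- if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(as.numeric(m$config_digest), as.numeric(digest))) m
    else list(config_digest = digest, stages_done = character(0),
              artifacts = list())
  } else list(config_digest = digest, stages_done = character(0),
              artifacts = list())
  done <- function(stage) stage %in% manifest$stages_done
  mark <- function(stage, artifacts) {
    manifest$stages_done <<- union(manifest$stages_done, stage)
    manifest$artifacts[[stage]] <<- artifacts
    manifest$package_version <<- as.character(utils::packageVersion("chirpnet"))
    manifest$seed <<- cfg$seed
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% stages || done(stage)) return(invisible(NULL))
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  fa <- cfg$preprocessing[c("n_fft", "hop")]

  run_stage("simulate", function() {
    dirs <- character(0)
    for (cid in names(cfg$simulate)) {
      args <- cfg$simulate[[cid]]
      args$collection_id <- cid
      if (is.null(args$seed)) args$seed <- cfg$seed + length(dirs)
      cc <- do.call(collection_config, args)
      d <- file.path(out, "data", cid)
      synth_collection(cc, d)
      dirs <- c(dirs, d)
    }
    mark("simulate", dirs)
  })

  load_collections <- function() {
    dirs <- list.dirs(file.path(out, "data"), recursive = FALSE)
    cols <- list()
    for (d in dirs) {
      catalog <- read_catalog(file.path(d, "catalog.csv"))
      cols[[basename(d)]] <- lapply(seq_len(nrow(catalog)), function(i) {
        r <- load_recording(catalog$file[i], catalog)
        r
      })
    }
    cols
  }

  run_stage("preprocess", function() {
    cols <- load_collections()
    cache <- file.path(out, "cache")
    dir.create(cache, showWarnings = FALSE)
    index <- list()
    for (cid in names(cols)) {
      sf <- do.call(segment_features,
                    c(list(recordings = cols[[cid]], type = "mfcc"),
                      cfg$preprocessing["n_fft"], cfg$preprocessing["hop"],
                      n_mfcc = cfg$preprocessing$n_mfcc,
                      n_mels = cfg$preprocessing$n_mels))
      saveRDS(sf, file.path(cache, paste0(cid, "_mfcc.rds")))
      sp <- do.call(segment_features,
                    c(list(recordings = cols[[cid]], type = "spectrogram"),
                      cfg$preprocessing["n_fft"], cfg$preprocessing["hop"]))
      saveRDS(sp, file.path(cache, paste0(cid, "_spec.rds")))
      index[[cid]] <- data.frame(collection = cid,
                                 n_segments = length(sf$labels))
    }
    write.csv(do.call(rbind, index), file.path(cache, "index.csv"),
              row.names = FALSE)
    mark("preprocess", file.path(out, "cache"))
  })

  run_stage("autoencoder", function() {
    cache <- file.path(out, "cache")
    specs <- list(); labels <- c()
    for (f in list.files(cache, pattern = "_spec\\.rds$", full.names = TRUE)) {
      sp <- readRDS(f)
      specs <- c(specs, sp$features)
      labels <- c(labels, sp$labels)
    }
    noise <- which(labels == "noise")
    set.seed(cfg$seed)
    take <- sample(noise, min(cfg$autoencoder$n_train_noise, length(noise)))
    ae <- build_autoencoder(seed = cfg$seed)
    tr <- train_autoencoder(ae, specs[take],
                            ae_config(cfg$autoencoder$learning_rate,
                                      cfg$autoencoder$batch_size,
                                      cfg$autoencoder$epochs,
                                      seed = cfg$seed))
    saveRDS(tr$model, file.path(out, "autoencoder.rds"))
    write.csv(data.frame(epoch = seq_along(tr$history), mse = tr$history),
              file.path(out, "ae_history.csv"), row.names = FALSE)
    mark("autoencoder", c(file.path(out, "autoencoder.rds"),
                          file.path(out, "ae_history.csv")))
  })

  run_stage("cluster", function() {
    cols <- load_collections()
    arts <- character(0)
    for (cid in names(cols)) {
      res <- run_noise_by_height(
        cols[[cid]], n_train = cfg$autoencoder$n_train_noise,
        n_embed = cfg$autoencoder$n_train_noise,
        ae_cfg = ae_config(cfg$autoencoder$learning_rate,
                           cfg$autoencoder$batch_size,
                           cfg$autoencoder$epochs, seed = cfg$seed),
        seed = cfg$seed, feature_args = fa,
        n_neighbors_grid = cfg$umap$n_neighbors_grid,
        min_dist_grid = cfg$umap$min_dist_grid)
      f1 <- file.path(out, paste0("umap_grid_", cid, ".csv"))
      write.csv(res$results, f1, row.names = FALSE)
      arts <- c(arts, f1)
      if (!is.null(res$best)) {
        bi <- as.integer(rownames(res$best))
        emb <- data.frame(x = res$embeddings[[bi]][, 1],
                          y = res$embeddings[[bi]][, 2],
                          label = res$labels,
                          n_neighbors = res$best$n_neighbors,
                          min_dist = res$best$min_dist)
        f2 <- file.path(out, paste0("umap_best_", cid, ".csv"))
        write.csv(emb, f2, row.names = FALSE)
        arts <- c(arts, f2)
      }
    }
    mark("cluster", arts)
  })

  run_stage("classify", function() {
    cols <- load_collections()
    arts <- character(0)
    for (task in cfg$tasks) {
      cc <- clf_config(task, epochs = cfg$classifier$epochs[[task]],
                       learning_rate = cfg$classifier$learning_rate,
                       batch_size = cfg$classifier$batch_size,
                       runs = cfg$classifier$runs, seed = cfg$seed)
      res <- joined_eval(cols, task, config = cc, ratios = cfg$split,
                         seed = cfg$seed, feature_args = fa)
      f1 <- file.path(out, paste0("f1_", task, ".csv"))
      write.csv(res$report, f1, row.names = FALSE)
      f2 <- file.path(out, paste0("confusion_", task, ".csv"))
      write.csv(as.data.frame(res$confusion), f2, row.names = TRUE)
      arts <- c(arts, f1, f2)
    }
    mark("classify", arts)
  })

  invisible(if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else manifest)
}
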