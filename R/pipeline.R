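# End-to-end orchestration of the five construction stages:
# (1) automatic landmarking of every raw mesh, (2) landmark-guided NICP
# against the template, (3) initial global PCA, (4) chi-square pruning of
# failed correspondences, (5) final (global and optionally bespoke) model
# builds plus evaluation curves. Per-subject failures are recorded and
# skipped, never fatal; stage outputs are cached on disk keyed by content
# hashes so reruns resume.

#' Pipeline configuration
#'
#' Validates paths and sub-configurations for [run_pipeline()].
#'
#' @param input_dir directory of raw meshes (`.ply` / `.obj`).
#' @param template_path template mesh file.
#' @param template_landmarks_path landmark JSON with `template_indices`.
#' @param output_dir run output directory (created).
#' @param demographics_csv optional demographics CSV (enables bespoke
#'   models).
#' @param detector a detector function, a `"pkg::fun"` string, or `NULL`
#'   when `detector_factory` is given.
#' @param detector_factory optional `function(subject_id, mesh)` returning a
#'   per-subject detector (e.g. built on per-subject ground truth JSONs).
#' @param cameras `NULL` for the default rig (computed per mesh) or a list
#'   of `virtual_camera`s.
#' @param image_size rendered view size for the default rig.
#' @param nicp an [nicp_config()].
#' @param p_f pruning plausibility level.
#' @param variance_to_retain model truncation rule.
#' @param bespoke build demographic sub-models (needs demographics).
#' @param bespoke_min_count minimum subjects per demographic group.
#' @param evaluation list of toggles: `compactness`, `generalization`,
#'   `specificity`, `holdout_frac`, `specificity_samples`.
#' @param seed integer seed for every stochastic step.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, template_path, template_landmarks_path,
                            output_dir,
                            demographics_csv = NULL,
                            detector = NULL, detector_factory = NULL,
                            cameras = NULL, image_size = c(512L, 512L),
                            nicp = nicp_config(),
                            p_f = 0.99, variance_to_retain = 0.995,
                            bespoke = FALSE, bespoke_min_count = 3L,
                            evaluation = list(),
                            seed = 1L, log_level = "info") {
  for (p in c(input_dir, template_path, template_landmarks_path))
    if (!file.exists(p)) stop("pipeline_config: path does not exist: ", p)
  if (!is.null(demographics_csv) && !file.exists(demographics_csv))
    stop("pipeline_config: path does not exist: ", demographics_csv)
  if (is.null(detector) && is.null(detector_factory))
    stop("pipeline_config: a detector or detector_factory is required")
  if (!inherits(nicp, "nicp_config")) stop("pipeline_config: invalid nicp config")
  ev <- utils::modifyList(list(compactness = TRUE, generalization = FALSE,
                               specificity = FALSE, holdout_frac = 0.2,
                               specificity_samples = 100L), evaluation)
  structure(list(input_dir = input_dir, template_path = template_path,
                 template_landmarks_path = template_landmarks_path,
                 output_dir = output_dir, demographics_csv = demographics_csv,
                 detector = detector, detector_factory = detector_factory,
                 cameras = cameras, image_size = as.integer(image_size),
                 nicp = nicp, p_f = p_f,
                 variance_to_retain = variance_to_retain,
                 bespoke = bespoke, bespoke_min_count = as.integer(bespoke_min_count),
                 evaluation = ev, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' All scalar fields of [pipeline_config()] can be given in a YAML file;
#' `nicp:` maps onto [nicp_config()] arguments; `detector:` is a
#' `"pkg::fun"` string resolved with [resolve_detector()].
#'
#' @param path YAML file.
#' @param ... overrides passed to [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$nicp)) y$nicp <- do.call(nicp_config, y$nicp)
  if (!is.null(y$detector) && is.character(y$detector))
    y$detector <- resolve_detector(y$detector)
  y <- utils::modifyList(y, list(...))
  do.call(pipeline_config, y)
}

pipe_log <- function(state, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  if (!identical(state$log_level, "quiet")) message(msg)
  cat(msg, "\n", file = state$log_file, append = TRUE)
}

# Content hash of files plus a configuration fingerprint.
content_hash <- function(files, extra = NULL) {
  h <- unname(tools::md5sum(files[file.exists(files)]))
  if (!is.null(extra)) {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(extra, tf, version = 2L)
    h <- c(h, unname(tools::md5sum(tf)))
  }
  tf2 <- tempfile()
  on.exit(unlink(tf2), add = TRUE)
  writeLines(h, tf2)
  unname(tools::md5sum(tf2))
}

cache_fresh <- function(out_file, hash_file, hash) {
  file.exists(out_file) && file.exists(hash_file) &&
    identical(readLines(hash_file, warn = FALSE)[1L], hash)
}

#' Run the full model-construction pipeline
#'
#' Executes landmarking, dense correspondence, the initial PCA, pruning and
#' the final model builds in order, writing all artifacts plus a JSON
#' manifest under `config$output_dir`. Per-subject landmarking or
#' registration failures are logged, recorded in the manifest with a reason,
#' and skipped. Fewer than 3 subjects surviving to the modelling stage is
#' fatal.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("landmarks", "corresponded", "pruning", "models", "evaluation"))
    dir.create(file.path(out, d), showWarnings = FALSE)
  state <- list(log_level = config$log_level,
                log_file = file.path(out, "run.log"))

  set.seed(config$seed)
  template <- read_mesh(config$template_path)
  template_landmarks <- read_landmarks(config$template_landmarks_path)
  if (is.null(template_landmarks$template_indices))
    stop("run_pipeline: template landmarks must carry template_indices")
  records <- if (!is.null(config$demographics_csv))
    read_demographics(config$demographics_csv)

  mesh_files <- sort(list.files(config$input_dir, "\\.(ply|obj)$",
                                full.names = TRUE))
  if (!length(mesh_files)) stop("run_pipeline: no meshes in ", config$input_dir)
  ids <- tools::file_path_sans_ext(basename(mesh_files))
  pipe_log(state, "pipeline start: ", length(ids), " subjects")

  nicp_fp <- list(nicp = unclass(config$nicp), image = config$image_size)
  subjects <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    rec <- list(subject_id = id, mesh_file = mesh_files[i],
                landmark = "pending", register = "pending", reason = NA)
    t0 <- proc.time()[["elapsed"]]
    lm_file <- file.path(out, "landmarks", paste0(id, ".json"))
    lm_hash_file <- paste0(lm_file, ".hash")
    lm_hash <- content_hash(mesh_files[i], extra = config$image_size)
    reg_file <- file.path(out, "corresponded", paste0(id, ".ply"))
    reg_hash_file <- paste0(reg_file, ".hash")

    res <- tryCatch({
      if (cache_fresh(lm_file, lm_hash_file, lm_hash)) {
        rec$landmark <- "cached"
      } else {
        mesh <- read_mesh(mesh_files[i])
        detector <- if (!is.null(config$detector_factory))
          config$detector_factory(id, mesh) else resolve_detector(config$detector)
        cameras <- if (is.null(config$cameras))
          default_camera_rig(mesh, image_size = config$image_size)
        else config$cameras
        lms <- auto_landmark(mesh, cameras, detector)
        write_landmarks(lms, lm_file)
        writeLines(lm_hash, lm_hash_file)
        rec$landmark <- "ok"
      }
      TRUE
    }, error = function(e) {
      rec$landmark <<- "failed"
      rec$reason <<- paste0("landmarking: ", conditionMessage(e))
      FALSE
    })
    rec$landmark_s <- round(proc.time()[["elapsed"]] - t0, 2)

    if (res) {
      t0 <- proc.time()[["elapsed"]]
      reg_hash <- content_hash(c(mesh_files[i], lm_file,
                                 config$template_path), extra = nicp_fp)
      res <- tryCatch({
        if (cache_fresh(reg_file, reg_hash_file, reg_hash)) {
          rec$register <- "cached"
        } else {
          mesh <- read_mesh(mesh_files[i])
          lms <- read_landmarks(lm_file)
          reg <- nicp_register(template, mesh, template_landmarks, lms,
                               config = config$nicp)
          write_registration(reg, reg_file, config = config$nicp)
          writeLines(reg_hash, reg_hash_file)
          rec$register <- "ok"
        }
        TRUE
      }, error = function(e) {
        rec$register <<- "failed"
        rec$reason <<- paste0("registration: ", conditionMessage(e))
        FALSE
      })
      rec$register_s <- round(proc.time()[["elapsed"]] - t0, 2)
    }
    if (!res) pipe_log(state, id, " failed: ", rec$reason)
    else pipe_log(state, id, " done (landmark ", rec$landmark,
                  ", register ", rec$register, ")")
    subjects[[id]] <- rec
  }

  ok_ids <- names(Filter(function(r) r$register %in% c("ok", "cached"),
                         subjects))
  if (length(ok_ids) < 3L)
    stop("run_pipeline: only ", length(ok_ids),
         " subjects survived to modelling (need >= 3); failures: ",
         paste(vapply(Filter(function(r) !is.na(r$reason), subjects),
                      `[[`, "", "reason"), collapse = " | "))

  pipe_log(state, "Procrustes + PCA over ", length(ok_ids), " subjects")
  corresponded <- lapply(ok_ids, function(id)
    read_mesh(file.path(out, "corresponded", paste0(id, ".ply"))))
  gpa <- generalized_procrustes(corresponded)
  shapes <- do.call(rbind, lapply(gpa$aligned, as_shape_vector))
  rownames(shapes) <- ok_ids

  pruned <- prune_and_rebuild(shapes, p_f = config$p_f, subject_ids = ok_ids,
                              variance_to_retain = config$variance_to_retain,
                              trilist = template$trilist)
  write_pruning_report(pruned$report,
                       file.path(out, "pruning", "scores.csv"),
                       file.path(out, "pruning", "summary.json"))
  pipe_log(state, "pruning flagged ", pruned$report$n_flagged, " / ",
           pruned$report$n_total)

  models <- list(global = pruned$model)
  survivors <- setdiff(ok_ids, pruned$report$flagged)
  if (config$bespoke && !is.null(records)) {
    rules <- default_bespoke_rules()
    recs <- records[match(survivors, records$subject_id), , drop = FALSE]
    keys <- vapply(seq_len(nrow(recs)), function(i) {
      key <- "global"
      for (rule in rules) {
        eth_ok <- is.null(rule$ethnicity) ||
          identical(rule$ethnicity, recs$ethnicity[i])
        if (eth_ok && recs$age[i] >= rule$age_min && recs$age[i] < rule$age_max) {
          key <- rule$key
          break
        }
      }
      key
    }, character(1L))
    used_rules <- list()
    for (rule in rules) {
      members <- survivors[keys == rule$key]
      if (length(members) >= config$bespoke_min_count) {
        models[[rule$key]] <- build_pca(
          shapes[members, , drop = FALSE],
          variance_to_retain = config$variance_to_retain,
          trilist = template$trilist)
        used_rules[[length(used_rules) + 1L]] <- rule
      }
    }
    if (length(used_rules)) {
      bset <- bespoke_model_set(models, rules = used_rules)
      save_model(bset, file.path(out, "models", "bespoke.rds"))
    }
  }
  save_model(models$global, file.path(out, "models", "global.rds"))

  ev <- config$evaluation
  if (isTRUE(ev$compactness))
    write_curve(compactness_curve(models$global),
                file.path(out, "evaluation", "compactness.csv"))
  if (isTRUE(ev$generalization) && length(survivors) >= 6L) {
    set.seed(config$seed + 1L)
    hold <- sample(survivors, max(2L, round(ev$holdout_frac * length(survivors))))
    train <- setdiff(survivors, hold)
    m_tr <- build_pca(shapes[train, , drop = FALSE],
                      variance_to_retain = config$variance_to_retain,
                      trilist = template$trilist)
    write_curve(generalization_curve(m_tr, shapes[hold, , drop = FALSE]),
                file.path(out, "evaluation", "generalization.csv"))
  }
  if (isTRUE(ev$specificity)) {
    sp <- specificity(models$global, shapes[survivors, , drop = FALSE],
                      n_samples = ev$specificity_samples,
                      seed = config$seed + 2L)
    jsonlite::write_json(list(mean = sp$mean, sd = sp$sd),
                         file.path(out, "evaluation", "specificity.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    schema_version = 1L,
    config = config_echo(config),
    n_attempted = length(ids),
    n_corresponded = length(ok_ids),
    n_flagged = pruned$report$n_flagged,
    n_in_model = length(survivors),
    flagged = pruned$report$flagged,
    subjects = subjects,
    models = names(models))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  pipe_log(state, "pipeline complete: ", length(survivors), " subjects in model")
  invisible(manifest)
}

# JSON-serializable echo of the resolved configuration.
config_echo <- function(config) {
  e <- unclass(config)
  e$nicp <- unclass(e$nicp)
  for (f in c("detector", "detector_factory", "cameras"))
    if (!is.null(e[[f]]) && !is.character(e[[f]]))
      e[[f]] <- paste0("<", f, ">")
  e
}

#' Human-readable summary of a pipeline run
#'
#' Reads the manifest of a (possibly partial) run and prints per-stage
#' counts, flagged outliers, failure reasons and timings, cross-checked
#' against the artifacts on disk.
#'
#' @param output_dir a pipeline output directory.
#' @return the summary list, invisibly.
#' @export
manifest_report <- function(output_dir) {
  mf <- file.path(output_dir, "manifest.json")
  if (!file.exists(mf)) {
    cat("0 subjects (no manifest found in ", output_dir, ")\n", sep = "")
    return(invisible(list(n_attempted = 0L)))
  }
  m <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  subj <- m$subjects
  n_lm_ok <- sum(vapply(subj, function(s)
    s$landmark %in% c("ok", "cached"), logical(1L)))
  n_reg_ok <- sum(vapply(subj, function(s)
    s$register %in% c("ok", "cached"), logical(1L)))
  on_disk <- length(list.files(file.path(output_dir, "corresponded"),
                               "\\.ply$"))
  cat(sprintf("pipeline run: %d attempted\n", m$n_attempted))
  cat(sprintf("  landmarked:    %d\n", n_lm_ok))
  cat(sprintf("  corresponded:  %d (%d on disk)\n", n_reg_ok, on_disk))
  cat(sprintf("  flagged:       %d (%s)\n", m$n_flagged,
              paste(unlist(m$flagged), collapse = ", ")))
  cat(sprintf("  in final model: %d\n", m$n_in_model))
  failures <- Filter(function(s) !is.null(s$reason) && !is.na(s$reason), subj)
  if (length(failures)) {
    cat("  failures:\n")
    for (s in failures)
      cat(sprintf("    %s: %s\n", s$subject_id, s$reason))
  }
  total_s <- sum(vapply(subj, function(s)
    (if (is.null(s$landmark_s)) 0 else s$landmark_s) +
      (if (is.null(s$register_s)) 0 else s$register_s), numeric(1L)))
  cat(sprintf("  total subject processing time: %.1f s\n", total_s))
  invisible(list(n_attempted = m$n_attempted, n_landmarked = n_lm_ok,
                 n_corresponded = n_reg_ok, n_on_disk = on_disk,
                 n_flagged = m$n_flagged, n_in_model = m$n_in_model,
                 failures = failures))
}
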