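#' Persist a simulated run or collection as plain text
#'
#' Each run is stored as a directory with `data.csv` (volumes x voxels),
#' `labels.tsv` (per-volume condition labels) and `meta.json` (paradigm,
#' CNR, seeds). A collection adds a top-level `collection.json` index.
#'
#' @param run a `simulated_run`.
#' @param dir target directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "simulated_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(run$data),
                     file.path(dir, "data.csv"))
  data.table::fwrite(data.frame(volume = seq_along(run$volume_labels),
                                label = run$volume_labels),
                     file.path(dir, "labels.tsv"), sep = "\t")
  meta <- list(cnr = run$cnr, noise_sd = run$noise_sd,
               subject_id = run$subject_id, seed = run$seed,
               group = run$group, grid = run$grid,
               paradigm = run$paradigm[c("n_tasks", "blocks_per_task",
                                         "task_seconds", "rest_seconds",
                                         "tr_seconds", "order", "seed")])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  data <- as.matrix(data.table::fread(file.path(dir, "data.csv")))
  dimnames(data) <- NULL
  par <- make_paradigm(n_tasks = meta$paradigm$n_tasks,
                       blocks_per_task = meta$paradigm$blocks_per_task,
                       task_seconds = meta$paradigm$task_seconds,
                       rest_seconds = meta$paradigm$rest_seconds,
                       tr_seconds = meta$paradigm$tr_seconds,
                       order = meta$paradigm$order)
  structure(list(data = data, volume_labels = par$volume_labels,
                 paradigm = par, cnr = meta$cnr, noise_sd = meta$noise_sd,
                 source_map = NULL, subject_id = meta$subject_id,
                 seed = meta$seed, group = meta$group, grid = meta$grid),
            class = "simulated_run")
}

#' @rdname write_run
#' @param collection a `sim_collection` from [generate_group()].
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "sim_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- list(group = collection$group, n_subjects = collection$n_subjects,
                cnr_levels = collection$cnr_levels, seed = collection$seed,
                grid = collection$grid, datasets = list())
  for (i in seq_along(collection$datasets)) {
    ds <- collection$datasets[[i]]
    name <- sprintf("ds_s%02d_cnr%s", ds$subject, format(ds$cnr))
    write_run(ds$train, file.path(dir, name, "train"))
    write_run(ds$test, file.path(dir, name, "test"))
    index$datasets[[i]] <- list(name = name, subject = ds$subject,
                                cnr = ds$cnr, group = ds$group)
  }
  jsonlite::write_json(index, file.path(dir, "collection.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_run
#' @export
read_collection <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "collection.json"),
                               simplifyVector = FALSE)
  datasets <- lapply(index$datasets, function(e)
    list(subject = e$subject, cnr = e$cnr, group = e$group,
         train = read_run(file.path(dir, e$name, "train")),
         test = read_run(file.path(dir, e$name, "test"))))
  structure(list(datasets = datasets, group = index$group,
                 n_subjects = index$n_subjects,
                 cnr_levels = unlist(index$cnr_levels), seed = index$seed,
                 grid = index$grid),
            class = "sim_collection")
}
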