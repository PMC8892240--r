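#' Save a fitted model as plain-text files
#'
#' Writes the dictionary, the stacked projection, the per-band effective
#' projections and the training history as CSV files plus a JSON metadata
#' file, so a model can be stored, inspected and reloaded without any
#' binary format.
#'
#' @param model a fitted `mbcc_model`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_mbcc_model <- function(model, dir) {
  stopifnot(inherits(model, "mbcc_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, name)
    utils::write.table(m, file.path(dir, paste0(name, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  wm(model$dictionary$D, "dictionary")
  wm(model$projections$stacked, "projection_stacked")
  for (m in seq_len(model$M))
    wm(model$projections$Gband[[m]], sprintf("projection_band%d", m))
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  meta <- list(method = model$method, band_names = model$band_names,
               d = model$d, M = model$M, C = model$C,
               label_values = model$label_values,
               atoms_per_class = model$dictionary$atoms_per_class,
               config = unclass(model$config))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Load a model saved by [write_mbcc_model()]
#'
#' @param dir directory holding the model files.
#' @return An `mbcc_model`.
#' @export
read_mbcc_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  rm_ <- function(name)
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".csv")), sep = ","))
  D <- unname(rm_("dictionary"))
  G <- unname(rm_("projection_stacked"))
  Gband <- lapply(seq_len(meta$M), function(m)
    unname(rm_(sprintf("projection_band%d", m))))
  cfg_args <- meta$config
  cfg_args$sigma <- cfg_args$sigma   # keep explicit sigma rather than 1 - alpha
  cfg <- do.call(mbcc_config, cfg_args)
  dict <- dictionary_model(D, meta$atoms_per_class, meta$C)
  if (meta$method == "mbcc") {
    proj <- split_projection(G, meta$d, meta$M, cfg$sigma)
  } else {
    proj <- list(G0 = NULL, Gtilde = Gband, Gband = Gband, sigma = 1,
                 stacked = G)
  }
  history <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(method = meta$method, config = cfg, projections = proj,
                 dictionary = dict, history = history,
                 band_names = meta$band_names, d = meta$d, M = meta$M,
                 C = meta$C, label_values = meta$label_values),
            class = "mbcc_model")
}
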