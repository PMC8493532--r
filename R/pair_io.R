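# On-disk format for rendered pairs: 8-bit grayscale PNG image, indexed
# (code-valued) PNG label, JSON provenance sidecar, and a dataset manifest.

#' Write a pseudo pair to disk
#'
#' Writes `<id>_img.png` (8-bit grayscale), `<id>_lbl.png` (label codes as
#' 8-bit values) and `<id>.json` (provenance, cone geometry and task
#' legend).
#'
#' @param pair a `pseudo_pair`.
#' @param dir output directory (created if needed).
#' @param id file stem.
#' @return `id`, invisibly.
#' @export
write_pseudo_pair <- function(pair, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(pair$image, file.path(dir, paste0(id, "_img.png")))
  png::writePNG(pair$label / 255, file.path(dir, paste0(id, "_lbl.png")))
  jsonlite::write_json(
    list(provenance = pair$provenance,
         task_legend = as.list(pair$task_legend_map),
         cone = unclass(pair$cone)),
    file.path(dir, paste0(id, ".json")), auto_unbox = TRUE, digits = NA)
  invisible(id)
}

#' Read a pseudo pair written by [write_pseudo_pair()]
#' @param dir directory.
#' @param id file stem.
#' @return a `pseudo_pair` (image quantized to 8 bits; labels exact).
#' @export
read_pseudo_pair <- function(dir, id) {
  img <- png::readPNG(file.path(dir, paste0(id, "_img.png")))
  if (length(dim(img)) == 3) img <- img[, , 1]
  lblraw <- png::readPNG(file.path(dir, paste0(id, "_lbl.png")))
  if (length(dim(lblraw)) == 3) lblraw <- lblraw[, , 1]
  lbl <- matrix(as.integer(round(lblraw * 255)), nrow(lblraw))
  meta <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                              simplifyVector = TRUE)
  cone <- structure(meta$cone, class = "cone_geometry")
  lg <- unlist(meta$task_legend)
  attr(lbl, "task_legend") <- lg
  structure(list(image = img, label = lbl, cone = cone,
                 task_legend_map = lg, provenance = meta$provenance),
            class = "pseudo_pair")
}

#' Write a rendered dataset with manifest
#'
#' @param pairs list of `pseudo_pair`.
#' @param dir output directory.
#' @return path of the written `manifest.csv`, invisibly.
#' @export
write_dataset <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(pairs), function(i) {
    id <- sprintf("pair_%05d", i)
    write_pseudo_pair(pairs[[i]], dir, id)
    pv <- pairs[[i]]$provenance
    data.frame(id = id, model_id = pv$model_id, view = pv$view,
               crop_mode = pv$crop_mode, seed = pv$seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of `pseudo_pair`.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(manifest$id, function(id) read_pseudo_pair(dir, id))
}
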