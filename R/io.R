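#' Serialize a genotype to disk
#'
#' Hosts are written as an edge-list CSV (`<path>.csv`: source_id,
#' target_id, coefficient) plus a JSON sidecar (`<path>.json`: architecture
#' tag and protein roster). Parasites are a single JSON record
#' (`<path>.json`).
#'
#' @param genotype a `pleio_host` or `pleio_parasite`.
#' @param path base path, written with `.csv` / `.json` extensions.
#' @return `path`, invisibly.
#' @seealso [load_genotype()]
#' @export
save_genotype <- function(genotype, path) {
  if (inherits(genotype, "pleio_host")) {
    edges <- genotype$edges
    names(edges) <- c("source_id", "target_id", "coefficient")
    # %.17g keeps the coefficients bit-exact through the text round-trip
    edges$coefficient <- sprintf("%.17g", edges$coefficient)
    write.csv(edges, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(type = "host", architecture = genotype$architecture,
           proteins = genotype$proteins,
           hash = genotype_hash(genotype)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (inherits(genotype, "pleio_parasite")) {
    jsonlite::write_json(
      list(type = "parasite",
           target_index = genotype$target_index,
           target_coefficient = genotype$target_coefficient,
           self_coefficient = genotype$self_coefficient,
           detector_coefficient = genotype$detector_coefficient),
      paste0(path, ".json"), auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  } else stop("genotype must be a pleio_host or pleio_parasite")
  invisible(path)
}

#' Load a genotype from disk
#'
#' Reads the files written by [save_genotype()] and validates hosts against
#' the model's structural rules (detector-effector edges, coefficient
#' ranges, roster invariants), rejecting malformed files.
#'
#' @param path base path used when saving (no extension).
#' @return a `pleio_host` or `pleio_parasite`.
#' @export
load_genotype <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$type, "parasite")) {
    return(structure(
      list(target_index = as.integer(meta$target_index),
           target_coefficient = as.numeric(meta$target_coefficient),
           self_coefficient = as.numeric(meta$self_coefficient),
           detector_coefficient = as.numeric(meta$detector_coefficient)),
      class = "pleio_parasite"))
  }
  if (!identical(meta$type, "host")) stop("unrecognized genotype file")
  proteins <- as.data.frame(meta$proteins)
  proteins$id <- as.integer(proteins$id)
  edges <- read.csv(paste0(path, ".csv"))
  edges <- data.frame(source = as.integer(edges$source_id),
                      target = as.integer(edges$target_id),
                      coefficient = as.numeric(edges$coefficient))
  host <- new_host(meta$architecture, proteins, edges)
  validate_host(host)
  host
}

write_manifest <- function(out_dir, cfg, seed, extra = list()) {
  manifest <- c(list(
    package = "pleionet",
    version = as.character(utils::packageVersion("pleionet")),
    seed = seed,
    config = unclass(cfg)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}
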