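# On-disk interchange: movies as one multi-page TIFF per channel with a
# JSON sidecar for metadata; click scripts and duration tables as CSV;
# lineage trees as JSON; allele sets as FASTA.

#' Write a FUCCI movie to disk
#'
#' `<stem>_red.tif` and `<stem>_green.tif` (multi-page, 8- or 16-bit) plus
#' `<stem>_meta.json` carrying the frame interval and bit depth.
#'
#' @param movie A `fucci_movie`.
#' @param stem Path stem (directories must exist).
#' @return The stem, invisibly.
#' @export
write_movie <- function(movie, stem) {
  check(inherits(movie, "fucci_movie"), "`movie` must be a fucci_movie")
  bit <- if (!is.null(movie$config)) movie$config$bit_depth else 16L
  maxval <- 2^bit - 1
  aslist <- function(a) lapply(seq_len(dim(a)[3]), function(f) a[, , f] / maxval)
  tiff::writeTIFF(aslist(movie$red), paste0(stem, "_red.tif"),
                  bits.per.sample = bit)
  tiff::writeTIFF(aslist(movie$green), paste0(stem, "_green.tif"),
                  bits.per.sample = bit)
  jsonlite::write_json(
    list(frame_interval_min = movie$frame_interval_min, bit_depth = bit,
         n_frames = dim(movie$red)[3], height = dim(movie$red)[1],
         width = dim(movie$red)[2]),
    paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Read a FUCCI movie written by [write_movie()]
#'
#' @param stem Path stem.
#' @return A `fucci_movie` (intensities restored to native counts).
#' @export
read_movie <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  maxval <- 2^meta$bit_depth - 1
  rd <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    a <- array(0, c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages)) a[, , f] <- round(pages[[f]] * maxval)
    a
  }
  structure(list(red = rd(paste0(stem, "_red.tif")),
                 green = rd(paste0(stem, "_green.tif")),
                 frame_interval_min = meta$frame_interval_min,
                 config = NULL),
            class = "fucci_movie")
}

#' Write / read a click script CSV (`frame,x,y,cell_id,parent_id`)
#'
#' @param clicks Click script data.frame.
#' @param path CSV path.
#' @return `write_click_script`: the path invisibly; `read_click_script`:
#'   the validated script.
#' @export
write_click_script <- function(clicks, path) {
  utils::write.csv(click_script(clicks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_click_script
#' @export
read_click_script <- function(path) {
  click_script(utils::read.csv(path))
}

#' Write / read a duration table CSV
#' (`cell_id,genotype,phase,duration_min,censored`)
#'
#' @param durations Duration table.
#' @param path CSV path.
#' @return `write_durations`: the path invisibly; `read_durations`: the
#'   table.
#' @export
write_durations <- function(durations, path) {
  utils::write.csv(durations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_durations
#' @export
read_durations <- function(path) {
  utils::read.csv(path)
}

#' Serialize a lineage tree to JSON
#'
#' Cells with their per-frame centroids/areas, division edges and end
#' reasons; round-trips through [read_lineage_json()].
#'
#' @param tree A `lineage_tree`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_lineage_json <- function(tree, path) {
  check(inherits(tree, "lineage_tree"), "`tree` must be a lineage_tree")
  jsonlite::write_json(
    list(info = tree$info, edges = tree$edges, tracks = tree$tracks,
         policy = tree$policy),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_lineage_json
#' @export
read_lineage_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tracks <- lapply(obj$tracks, function(tr) {
    tr <- as.data.frame(tr)
    tr$x <- as.numeric(tr$x); tr$y <- as.numeric(tr$y)
    tr$area <- as.integer(tr$area)
    tr
  })
  structure(list(tracks = tracks, info = as.data.frame(obj$info),
                 edges = as.data.frame(obj$edges), policy = obj$policy),
            class = "lineage_tree")
}

#' Write an allele set to FASTA
#'
#' @param alleles A `DNAStringSet` (e.g. from [simulate_alleles()]).
#' @param path FASTA path.
#' @return The path, invisibly.
#' @export
write_alleles <- function(alleles, path) {
  Biostrings::writeXStringSet(alleles, path)
  invisible(path)
}

#' Read an allele set from FASTA
#'
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
read_alleles <- function(path) {
  Biostrings::readDNAStringSet(path)
}
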