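#' Write / read particle coordinates as XYZ trajectory frames
#'
#' Standard XYZ text format, one frame per call (append to accumulate a
#' trajectory). Coordinates are written in nanometres with element tags
#' A (actin), S (spectrin), K (ankyrin).
#'
#' @param system An `axskel_system`.
#' @param path Output path.
#' @param append Append a frame to an existing file?
#' @param comment Comment line for the frame.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path, append = FALSE, comment = "axskel frame") {
  us <- system$config$us
  tags <- c("A", "S", "K")[system$kind + 1L]
  pos <- system$pos * us$sigma_nm
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), comment), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", tags, pos[, 1], pos[, 2], pos[, 3]),
             con)
  invisible(path)
}

#' @rdname write_xyz
#' @param frame Which frame to read (1-based).
#' @return `read_xyz()` returns a list with `tags` (character) and `pos`
#'   (N x 3 matrix, nm).
#' @export
read_xyz <- function(path, frame = 1) {
  lines <- readLines(path)
  i <- 1L
  for (f in seq_len(frame)) {
    n <- as.integer(lines[i])
    start <- i + 2L
    if (f == frame) {
      body <- lines[start:(start + n - 1L)]
      parts <- strsplit(trimws(body), "\\s+")
      tags <- vapply(parts, `[`, "", 1L)
      pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      return(list(tags = tags, pos = pos))
    }
    i <- start + n
  }
}

#' Write a topology sidecar as JSON
#'
#' Serializes the bond lists, angle triplets, junction pairs and state,
#' ring membership and FENE angle parameters to a JSON file.
#'
#' @param topology A topology list from a builder.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  jsonlite::write_json(topology, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  t <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("ss_bonds", "aa_bonds", "angles", "sk_bonds", "as_pairs")) {
    m <- t[[f]]
    ncols <- if (f == "angles") 3L else 2L
    if (length(m) == 0) m <- matrix(0L, 0, ncols)
    t[[f]] <- matrix(as.integer(m), ncol = ncols)
  }
  for (f in c("as_state", "as_filament", "ring_id", "filament_id", "n_rings"))
    t[[f]] <- as.integer(t[[f]])
  t
}
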