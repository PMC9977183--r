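#' Landmark dataset
#'
#' Container for a set of 3D landmark configurations. Every specimen must
#' carry the same number of landmarks `p`; coordinates are stored as a
#' `p x 3 x n` array with specimen ids along the third dimension.
#'
#' @param coords numeric `p x 3 x n` array of landmark coordinates (length
#'   units, e.g. mm), or a list of `p x 3` matrices.
#' @param specimen_id character vector of `n` unique specimen identifiers.
#' @param species_id character vector of `n` species identifiers (one per
#'   specimen; repeated across conspecific specimens).
#' @return An object of class `landmark_set` with elements `coords`,
#'   `specimen_id`, `species_id`, `p`, `n`.
#' @export
landmark_set <- function(coords, specimen_id, species_id) {
  if (is.list(coords)) {
    ps <- vapply(coords, nrow, integer(1))
    if (length(unique(ps)) != 1L) {
      bad <- if (!is.null(names(coords))) names(coords) else as.character(seq_along(coords))
      bad <- bad[ps != stats::median(ps)]
      stop("ragged landmark counts: specimen(s) ", paste(bad, collapse = ", "),
           " differ from the rest", call. = FALSE)
    }
    coords <- array(unlist(coords),
                    dim = c(unname(ps[1]), 3L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  p <- dim(coords)[1]
  n <- dim(coords)[3]
  specimen_id <- as.character(specimen_id)
  species_id <- as.character(species_id)
  if (length(specimen_id) != n || length(species_id) != n)
    stop("specimen_id and species_id must each have one entry per configuration",
         call. = FALSE)
  if (anyDuplicated(specimen_id))
    stop("duplicated specimen ids: ",
         paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "),
         call. = FALSE)
  if (p < 4L)
    stop("at least 4 landmarks are required (got ", p, ")", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite landmark coordinates", call. = FALSE)
  dimnames(coords) <- list(NULL, c("x", "y", "z"), specimen_id)
  structure(list(coords = coords, specimen_id = specimen_id,
                 species_id = species_id, p = p, n = n),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set: ", x$n, " specimens, ", x$p, " 3D landmarks, ",
      length(unique(x$species_id)), " species\n", sep = "")
  invisible(x)
}

#' Subset a landmark set by specimen
#'
#' @param x a `landmark_set`.
#' @param keep logical or integer index over specimens, or character vector of
#'   specimen ids.
#' @return A `landmark_set` restricted to the selected specimens.
#' @export
subset_landmarks <- function(x, keep) {
  stopifnot(inherits(x, "landmark_set"))
  if (is.character(keep)) keep <- match(keep, x$specimen_id)
  landmark_set(x$coords[, , keep, drop = FALSE],
               x$specimen_id[keep], x$species_id[keep])
}

#' Read landmark configurations from TPS or long-format CSV
#'
#' TPS files are parsed as `LM3=` blocks followed by `p` coordinate lines,
#' with `ID=` holding the specimen id and `IMAGE=` the species id. The CSV
#' dialect is long format with columns `specimen_id, species_id,
#' landmark_index, x, y, z` and 0-based landmark indices.
#'
#' @param path path to the file.
#' @param format `"tps"` or `"csv"`; guessed from the extension by default.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  switch(format, tps = .read_tps(path), csv = .read_landmark_csv(path))
}

.read_tps <- function(path) {
  lines <- readLines(path)
  i <- 1L
  cfgs <- list(); spec <- character(); spp <- character()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM3?=", ln))
      stop("TPS parse error at line ", i, ": expected LM3= block header",
           call. = FALSE)
    p <- as.integer(sub("^LM3?=", "", ln))
    m <- matrix(NA_real_, p, 3L)
    for (j in seq_len(p)) {
      i <- i + 1L
      xyz <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
      if (length(xyz) != 3L || anyNA(xyz))
        stop("TPS parse error at line ", i, ": expected 3 numeric coordinates",
             call. = FALSE)
      m[j, ] <- xyz
    }
    id <- paste0("specimen_", length(cfgs) + 1L)
    img <- NA_character_
    while (i < length(lines) &&
           grepl("^(ID|IMAGE|SCALE|COMMENT)=", trimws(lines[i + 1L]))) {
      i <- i + 1L
      key <- trimws(lines[i])
      if (grepl("^ID=", key)) id <- sub("^ID=", "", key)
      if (grepl("^IMAGE=", key)) img <- sub("^IMAGE=", "", key)
    }
    cfgs[[length(cfgs) + 1L]] <- m
    spec <- c(spec, id)
    spp <- c(spp, if (is.na(img)) id else img)
    i <- i + 1L
  }
  names(cfgs) <- spec
  landmark_set(cfgs, spec, spp)
}

.read_landmark_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species_id", "landmark_index", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (cc in c("x", "y", "z")) {
    if (!is.numeric(d[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[cc]]))))[1]
      stop("non-numeric coordinate in column '", cc, "' at data line ", bad,
           call. = FALSE)
    }
  }
  sp <- split(d, d$specimen_id)
  counts <- vapply(sp, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    mode_p <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
    stop("ragged landmark counts: specimen(s) ",
         paste(names(counts)[counts != mode_p], collapse = ", "),
         " do not have ", mode_p, " landmarks", call. = FALSE)
  }
  # preserve first-appearance specimen order
  ord <- unique(d$specimen_id)
  cfgs <- lapply(sp[ord], function(b) {
    b <- b[order(b$landmark_index), ]
    if (!identical(as.integer(b$landmark_index), seq_len(nrow(b)) - 1L))
      stop("specimen ", b$specimen_id[1],
           ": landmark_index must be 0..p-1 without gaps", call. = FALSE)
    as.matrix(b[, c("x", "y", "z")])
  })
  species <- vapply(sp[ord], function(b) b$species_id[1], character(1))
  landmark_set(cfgs, ord, unname(species))
}

#' Write landmark configurations to TPS or long-format CSV
#'
#' @param x a `landmark_set`.
#' @param path output file path.
#' @param format `"tps"` or `"csv"` (see [read_landmarks()] for the dialects).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path, format = c("tps", "csv")) {
  stopifnot(inherits(x, "landmark_set"))
  format <- match.arg(format)
  if (format == "tps") {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(x$n)) {
      writeLines(sprintf("LM3=%d", x$p), con)
      writeLines(apply(x$coords[, , i], 1,
                       function(r) paste(format(r, digits = 17), collapse = " ")),
                 con)
      writeLines(sprintf("ID=%s", x$specimen_id[i]), con)
      writeLines(sprintf("IMAGE=%s", x$species_id[i]), con)
    }
  } else {
    d <- do.call(rbind, lapply(seq_len(x$n), function(i) {
      data.frame(specimen_id = x$specimen_id[i], species_id = x$species_id[i],
                 landmark_index = seq_len(x$p) - 1L,
                 x = x$coords[, 1, i], y = x$coords[, 2, i], z = x$coords[, 3, i])
    }))
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}
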