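#' Read one chromosome from a single-resolution cooler file
#'
#' Extracts the dense intra-chromosomal matrix for `chrom` from a
#' `.cool` file (HDF5, single resolution). Pixels are stored sparsely as
#' upper-triangle `(bin1_id, bin2_id, count)` records; missing pixels
#' are filled with zero and the stored triangle is mirrored, so the
#' returned matrix is symmetric. Bins are 0-based half-open genomic
#' intervals.
#'
#' @param path path to a `.cool` file.
#' @param chrom chromosome name to extract.
#' @param resolution_bp expected bin size; checked against the file.
#' @return A raw-count [contact_map()].
#' @seealso [write_cooler()], [read_triplet_text()]
#' @export
read_cooler <- function(path, chrom, resolution_bp) {
  if (!file.exists(path)) stop("cooler file not found: ", path)
  h <- tryCatch(rhdf5::h5ls(path, recursive = TRUE),
                error = function(e) stop("not a readable HDF5/cooler file: ", path))
  if (!all(c("chroms", "bins", "pixels") %in% h$name[h$group == "/"]))
    stop("file lacks cooler groups (chroms/bins/pixels): ", path)

  chrom_names <- as.character(rhdf5::h5read(path, "chroms/name"))
  ci <- match(chrom, chrom_names)
  if (is.na(ci))
    stop("chromosome '", chrom, "' not in file; available: ",
         paste(chrom_names, collapse = ", "))

  starts <- as.numeric(rhdf5::h5read(path, "bins/start"))
  ends <- as.numeric(rhdf5::h5read(path, "bins/end"))
  bin_chrom <- rhdf5::h5read(path, "bins/chrom")
  bin_chrom <- if (is.numeric(bin_chrom)) as.integer(bin_chrom) + 1L
               else match(as.character(bin_chrom), chrom_names)
  res <- stats::median(ends - starts)
  if (!is.na(resolution_bp) && res != resolution_bp)
    stop("file resolution ", res, " bp does not match requested ",
         resolution_bp, " bp")

  sel <- which(bin_chrom == ci)
  n <- length(sel)
  if (n == 0L) stop("chromosome '", chrom, "' has no bins in file")
  offset <- sel[1L] - 1L  # global id of this chromosome's first bin (0-based)

  b1 <- as.numeric(rhdf5::h5read(path, "pixels/bin1_id"))
  b2 <- as.numeric(rhdf5::h5read(path, "pixels/bin2_id"))
  cnt <- as.numeric(rhdf5::h5read(path, "pixels/count"))
  keep <- b1 >= offset & b1 < offset + n & b2 >= offset & b2 < offset + n
  m <- matrix(0, n, n)
  if (any(keep)) {
    i <- b1[keep] - offset + 1L
    j <- b2[keep] - offset + 1L
    # fold everything onto the upper triangle (tolerates duplicates and
    # lower-triangle storage), then mirror
    lo <- pmin(i, j); hi <- pmax(i, j)
    acc <- tapply(cnt[keep], list(idx = (hi - 1L) * n + lo), sum)
    pos <- as.integer(names(acc))
    m[pos] <- as.numeric(acc)
    m <- mirror_upper(m)
  }
  contact_map(m, chrom = chrom, resolution_bp = as.integer(res))
}

#' Write a ContactMap as a single-resolution cooler file
#'
#' Emits the standard single-resolution cooler HDF5 layout
#' (`chroms`, `bins`, `pixels`, `indexes` plus the usual root
#' attributes) holding one chromosome, storing only non-zero
#' upper-triangle pixels. [read_cooler()] inverts it exactly for
#' integer maps.
#'
#' @param map a [contact_map()].
#' @param path output path (`.cool`).
#' @return `path`, invisibly.
#' @export
write_cooler <- function(map, path) {
  validate_contact_map(map)
  if (file.exists(path)) file.remove(path)
  tmp <- paste0(path, ".tmp")
  if (file.exists(tmp)) file.remove(tmp)
  n <- map$n_bins
  res <- map$resolution_bp
  m <- map$matrix
  ut <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]

  rhdf5::h5createFile(tmp)
  for (g in c("chroms", "bins", "pixels", "indexes"))
    rhdf5::h5createGroup(tmp, g)
  rhdf5::h5write(map$chrom, tmp, "chroms/name")
  rhdf5::h5write(as.numeric(n) * res, tmp, "chroms/length")
  rhdf5::h5write(rep(0L, n), tmp, "bins/chrom")
  rhdf5::h5write(as.numeric(0:(n - 1L)) * res, tmp, "bins/start")
  rhdf5::h5write(as.numeric(1:n) * res, tmp, "bins/end")
  rhdf5::h5write(as.numeric(ut[, 1L] - 1L), tmp, "pixels/bin1_id")
  rhdf5::h5write(as.numeric(ut[, 2L] - 1L), tmp, "pixels/bin2_id")
  rhdf5::h5write(m[ut], tmp, "pixels/count")
  # bin1_offset: for each bin, index of its first pixel (CSR-style)
  cnts <- tabulate(ut[, 1L], nbins = n)
  rhdf5::h5write(c(0, cumsum(cnts)), tmp, "indexes/bin1_offset")
  rhdf5::h5write(c(0, nrow(ut)), tmp, "indexes/chrom_offset")

  fid <- rhdf5::H5Fopen(tmp)
  rhdf5::h5writeAttribute("HDF5::Cooler", fid, "format")
  rhdf5::h5writeAttribute(3L, fid, "format-version")
  rhdf5::h5writeAttribute(as.integer(res), fid, "bin-size")
  rhdf5::h5writeAttribute("fixed", fid, "bin-type")
  rhdf5::h5writeAttribute(as.integer(n), fid, "nbins")
  rhdf5::h5writeAttribute(1L, fid, "nchroms")
  rhdf5::h5writeAttribute(nrow(ut), fid, "nnz")
  rhdf5::h5writeAttribute(if (map$is_normalized) "normalized" else "counts",
                          fid, "storage-mode")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  file.rename(tmp, path)
  invisible(path)
}

#' Read a contact map from triplet text
#'
#' Plain-text interchange format: header lines `#chrom <name>`,
#' `#resolution <bp>`, `#nbins <n>`, then tab- or space-separated
#' `bin_i bin_j count` records with `bin_i <= bin_j`, 0-based. Duplicate
#' `(i, j)` records are summed; the stored upper triangle is mirrored.
#'
#' @param path path to the text file.
#' @return A [contact_map()] (raw counts).
#' @export
read_triplet_text <- function(path) {
  if (!file.exists(path)) stop("triplet file not found: ", path)
  lines <- readLines(path)
  hdr <- list(chrom = NA_character_, resolution = NA, nbins = NA)
  body_start <- 1L
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "") { body_start <- k + 1L; next }
    if (!startsWith(ln, "#")) { body_start <- k; break }
    parts <- strsplit(sub("^#", "", ln), "[ \t]+")[[1L]]
    key <- parts[1L]
    if (key == "chrom") hdr$chrom <- parts[2L]
    else if (key == "resolution") hdr$resolution <- as.numeric(parts[2L])
    else if (key == "nbins") hdr$nbins <- as.integer(parts[2L])
    body_start <- k + 1L
  }
  if (is.na(hdr$nbins)) stop("missing '#nbins' header in ", path)
  if (is.na(hdr$chrom)) hdr$chrom <- "chr?"
  if (is.na(hdr$resolution)) hdr$resolution <- 40000
  n <- hdr$nbins
  m <- matrix(0, n, n)
  if (body_start <= length(lines)) {
    for (k in body_start:length(lines)) {
      ln <- trimws(lines[k])
      if (ln == "" || startsWith(ln, "#")) next
      f <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1L]]))
      if (length(f) != 3L || anyNA(f))
        stop("malformed triplet line ", k, " in ", path, ": '", lines[k], "'")
      i <- f[1L]; j <- f[2L]
      if (i < 0 || j < 0 || i >= n || j >= n)
        stop("bin index out of range [0, ", n, ") on line ", k, " in ", path)
      if (i > j) { tmp <- i; i <- j; j <- tmp }
      m[i + 1L, j + 1L] <- m[i + 1L, j + 1L] + f[3L]
    }
  }
  m <- mirror_upper(m)
  contact_map(m, chrom = hdr$chrom, resolution_bp = as.integer(hdr$resolution))
}

#' Write a contact map as triplet text
#'
#' Writes the header and the non-zero upper triangle (diagonal
#' included) in row-major order. Round trip through
#' [read_triplet_text()] is exact for integer counts.
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_triplet_text <- function(map, path) {
  validate_contact_map(map)
  m <- map$matrix
  ut <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  writeLines(c(paste("#chrom", map$chrom),
               paste("#resolution", map$resolution_bp),
               paste("#nbins", map$n_bins)), con)
  if (nrow(ut))
    writeLines(paste(ut[, 1L] - 1L, ut[, 2L] - 1L,
                     format(m[ut], trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read or write a contact map, format chosen by file extension
#'
#' `.cool` files go through [read_cooler()] / [write_cooler()]; anything
#' else uses the triplet text format.
#'
#' @param path file path.
#' @param chrom,resolution_bp passed to [read_cooler()] for `.cool`
#'   input (`chrom = NULL` picks the first chromosome in the file).
#' @return A [contact_map()] for `read_contact_map`; the path invisibly
#'   for `write_contact_map`.
#' @export
read_contact_map <- function(path, chrom = NULL, resolution_bp = NA) {
  if (grepl("\\.cool$", path)) {
    if (is.null(chrom))
      chrom <- as.character(rhdf5::h5read(path, "chroms/name"))[1L]
    read_cooler(path, chrom, resolution_bp)
  } else read_triplet_text(path)
}

#' @rdname read_contact_map
#' @param map a [contact_map()].
#' @export
write_contact_map <- function(map, path) {
  if (grepl("\\.cool$", path)) write_cooler(map, path)
  else write_triplet_text(map, path)
}
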