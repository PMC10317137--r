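#' Write reflections, observations and components to columnar text
#'
#' Native plain-text format: comment header lines carrying the unit cell and
#' component ids, then one whitespace-separated row per reflection with
#' columns `h k l f_obs i_obs re_<id> im_<id> ...`. Rows are ordered
#' lexicographically on (h, k, l) and floats are serialized round-trip
#' exact (`%.17g`).
#'
#' @param path Output file path.
#' @param miller A [miller_set()].
#' @param obs An [observed_data()] (optional; zeros written if NULL).
#' @param components List of aligned [component()]s (optional).
#' @return `path`, invisibly.
#' @export
write_reflections <- function(path, miller, obs = NULL, components = NULL) {
  stopifnot(inherits(miller, "miller_set"))
  n <- n_reflections(miller)
  if (is.null(obs)) obs <- observed_data(f_obs = numeric(n))
  stopifnot(length(obs$f_obs) == n)
  ids <- character(0)
  cols <- list(h = miller$hkl[, 1], k = miller$hkl[, 2], l = miller$hkl[, 3],
               f_obs = obs$f_obs, i_obs = obs$i_obs)
  if (!is.null(components)) {
    fmat <- component_matrix(components, n)
    ids <- colnames(fmat)
    for (j in seq_along(ids)) {
      cols[[paste0("re_", ids[j])]] <- Re(fmat[, j])
      cols[[paste0("im_", ids[j])]] <- Im(fmat[, j])
    }
  }
  ord <- order(miller$hkl[, 1], miller$hkl[, 2], miller$hkl[, 3])
  cl <- miller$cell
  hdr <- c(
    sprintf("# mcsf reflections 1"),
    sprintf("# cell %.17g %.17g %.17g %.17g %.17g %.17g",
            cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma),
    sprintf("# components %s", paste(ids, collapse = " ")),
    sprintf("# columns %s", paste(names(cols), collapse = " "))
  )
  body <- do.call(paste, c(lapply(cols, function(x) {
    if (is.integer(x)) sprintf("%d", x[ord]) else sprintf("%.17g", x[ord])
  }), sep = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a native reflection file
#'
#' @param path File written by [write_reflections()].
#' @return List with `miller` ([miller_set()]), `obs` ([observed_data()]),
#'   and `components` (possibly empty list).
#' @export
read_reflections <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  cell_line <- grep("^# cell ", hdr, value = TRUE)
  if (length(cell_line) != 1) stop("missing or duplicated '# cell' header")
  cp <- as.numeric(strsplit(trimws(sub("^# cell ", "", cell_line)), "\\s+")[[1]])
  if (length(cp) != 6 || any(!is.finite(cp))) stop("malformed cell header")
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])
  comp_line <- grep("^# components", hdr, value = TRUE)
  ids <- if (length(comp_line) == 1) {
    x <- trimws(sub("^# components", "", comp_line))
    if (nzchar(x)) strsplit(x, "\\s+")[[1]] else character(0)
  } else character(0)
  col_line <- grep("^# columns ", hdr, value = TRUE)
  if (length(col_line) != 1) stop("missing '# columns' header")
  col_names <- strsplit(trimws(sub("^# columns ", "", col_line)), "\\s+")[[1]]
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(data_idx) == 0) stop("no data rows")
  parsed <- strsplit(trimws(lines[data_idx]), "\\s+")
  bad <- which(lengths(parsed) != length(col_names))
  if (length(bad))
    stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                 data_idx[bad[1]], length(col_names), lengths(parsed)[bad[1]]))
  m <- matrix(as.numeric(unlist(parsed)), ncol = length(col_names), byrow = TRUE)
  colnames(m) <- col_names
  if (any(!is.finite(m)))
    stop(sprintf("malformed row at line %d: non-numeric field",
                 data_idx[which(rowSums(!is.finite(m)) > 0)[1]]))
  hkl <- m[, c("h", "k", "l"), drop = FALSE]
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key))
    stop(sprintf("duplicate hkl entries: %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  miller <- miller_set(hkl, cell)
  obs <- observed_data(f_obs = m[, "f_obs"],
                       i_obs = if ("i_obs" %in% col_names) m[, "i_obs"] else NULL)
  components <- lapply(ids, function(id) {
    re <- m[, paste0("re_", id)]
    im <- m[, paste0("im_", id)]
    component(id, complex(real = re, imaginary = im), kind = "external")
  })
  list(miller = miller, obs = obs, components = components)
}

#' Import amplitudes from an mmCIF-style reflection loop
#'
#' Minimal adapter reading `_refln.index_h/k/l` and an amplitude column
#' (`_refln.F_meas_au` or `_refln.F_meas`) from a CIF reflection loop, plus
#' `_cell.length_*` / `_cell.angle_*` items.
#'
#' @param path mmCIF file path.
#' @return List with `miller` and `obs` (no components).
#' @export
read_mmcif_reflections <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  getval <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\s"), lines, value = TRUE)
    if (length(ln) == 0) stop(sprintf("missing %s", tag))
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  cell <- unit_cell(getval("_cell.length_a"), getval("_cell.length_b"),
                    getval("_cell.length_c"), getval("_cell.angle_alpha"),
                    getval("_cell.angle_beta"), getval("_cell.angle_gamma"))
  loop_starts <- grep("^\\s*loop_", lines)
  for (ls in loop_starts) {
    tags <- character(0)
    i <- ls + 1
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!all(c("_refln.index_h", "_refln.index_k", "_refln.index_l") %in% tags))
      next
    fcol <- intersect(c("_refln.F_meas_au", "_refln.F_meas"), tags)[1]
    if (is.na(fcol)) stop("no amplitude column in reflection loop")
    rows <- list()
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (!nzchar(tl) || grepl("^(_|loop_|#|data_)", tl)) break
      rows[[length(rows) + 1L]] <- strsplit(tl, "\\s+")[[1]]
      i <- i + 1
    }
    m <- do.call(rbind, rows)
    h <- as.integer(m[, match("_refln.index_h", tags)])
    k <- as.integer(m[, match("_refln.index_k", tags)])
    l <- as.integer(m[, match("_refln.index_l", tags)])
    f <- as.numeric(m[, match(fcol, tags)])
    keep <- is.finite(f) & !(h == 0 & k == 0 & l == 0)
    miller <- miller_set(cbind(h, k, l)[keep, , drop = FALSE], cell)
    return(list(miller = miller, obs = observed_data(f_obs = f[keep])))
  }
  stop("no reflection loop found")
}

#' Write a fitted scale table and run log
#'
#' @param fit A [fit_driver()] result.
#' @param path Output TSV path; the JSON run log goes to `<path>.log.json`.
#' @return `path`, invisibly.
#' @export
write_scale_table <- function(fit, path) {
  stopifnot(inherits(fit, "scale_set"))
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(attr(fit, "log"), paste0(path, ".log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
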