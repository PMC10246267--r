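# Bondi-type van der Waals radii (Angstrom). HOLE's own radius set
# differs slightly; absolute radii shift with the choice but the
# locations of the constriction minima do not. Override per call.
.vdw_bondi <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90, ZN = 1.39, MG = 1.73, CA = 2.31, "NA" = 2.27,
                K = 2.75, FE = 1.60, MN = 1.60)

.guess_element <- function(atom_name) {
  a <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(a, 1, 2))
  if (two %in% c("CL", "BR", "SE", "ZN", "MG", "FE", "MN")) return(two)
  toupper(substr(a, 1, 1))
}

#' Load a channel structure from PDB or mmCIF
#'
#' Minimal reader for the two standard text formats: ATOM records are
#' kept, hydrogens and waters are dropped, and HETATM/detergent records
#' are excluded unless `include_het = TRUE`. Each atom gets a
#' Bondi-type van der Waals radius (see `radius_overrides`); unknown
#' elements raise an error listing the offending atoms.
#'
#' @param path `.pdb` or `.cif` file
#' @param radius_overrides named vector of radii (Angstrom) that
#'   override or extend the built-in Bondi set
#' @param include_het keep HETATM records (default FALSE)
#' @param domains optional named list mapping domain labels (e.g.
#'   `"DI"`) to chain IDs or `chain:resno_range` strings
#' @return a `nav_structure`: `atoms` data.frame (`element`, `x`, `y`,
#'   `z`, `radius`, `resname`, `resno`, `chain`, `atom`, `domain`)
#' @export
load_structure <- function(path, radius_overrides = NULL,
                           include_het = FALSE, domains = NULL) {
  if (!file.exists(path)) .nav_stop("file not found", "navgate_io_error")
  ext <- tolower(tools::file_ext(path))
  atoms <- if (ext %in% c("cif", "mmcif")) .read_mmcif(path, include_het)
           else .read_pdb(path, include_het)
  atoms <- atoms[!(atoms$resname %in% c("HOH", "WAT", "DOD")), ,
                 drop = FALSE]
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (!nrow(atoms)) .nav_stop("no atoms left after filtering",
                              "navgate_io_error")
  rset <- .vdw_bondi
  if (!is.null(radius_overrides))
    rset[names(radius_overrides)] <- radius_overrides
  atoms$radius <- rset[atoms$element]
  if (anyNA(atoms$radius)) {
    bad <- unique(atoms$atom[is.na(atoms$radius)])
    .nav_stop(paste("no van der Waals radius for atoms:",
                    paste(utils::head(bad, 10), collapse = ", ")),
              "navgate_unknown_element")
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    .nav_stop("non-finite coordinates", "navgate_io_error")
  atoms$domain <- NA_character_
  if (!is.null(domains)) {
    for (d in names(domains)) {
      spec <- strsplit(domains[[d]], ":")[[1]]
      sel <- atoms$chain == spec[1]
      if (length(spec) > 1) {
        rr <- as.integer(strsplit(spec[2], "-")[[1]])
        sel <- sel & atoms$resno >= rr[1] & atoms$resno <= rr[2]
      }
      atoms$domain[sel] <- d
    }
  }
  structure(list(atoms = atoms, source = path), class = "nav_structure")
}

.read_pdb <- function(path, include_het) {
  ln <- readLines(path)
  rec <- substr(ln, 1, 6)
  keep <- rec == "ATOM  " | (include_het & rec == "HETATM")
  ln <- ln[keep]
  if (!length(ln)) .nav_stop("no ATOM records", "navgate_io_error")
  el <- trimws(substr(ln, 77, 78))
  name <- trimws(substr(ln, 13, 16))
  el[el == ""] <- vapply(name[el == ""], .guess_element, "")
  data.frame(
    atom = name,
    resname = trimws(substr(ln, 18, 20)),
    chain = trimws(substr(ln, 22, 22)),
    resno = as.integer(substr(ln, 23, 26)),
    x = as.numeric(substr(ln, 31, 38)),
    y = as.numeric(substr(ln, 39, 46)),
    z = as.numeric(substr(ln, 47, 54)),
    element = toupper(el))
}

.read_mmcif <- function(path, include_het) {
  ln <- readLines(path)
  # collect the _atom_site loop
  hdr_i <- grep("^_atom_site\\.", ln)
  if (!length(hdr_i)) .nav_stop("no _atom_site loop", "navgate_io_error")
  fields <- sub("^_atom_site\\.", "", trimws(ln[hdr_i]))
  body_start <- max(hdr_i) + 1
  body <- character()
  for (i in body_start:length(ln)) {
    l <- trimws(ln[i])
    if (l == "" || startsWith(l, "#") || startsWith(l, "_") ||
        startsWith(l, "loop_")) break
    body <- c(body, l)
  }
  toks <- strsplit(body, "[[:space:]]+")
  get <- function(row, f) {
    j <- match(f, fields)
    if (is.na(j)) NA_character_ else row[j]
  }
  rows <- lapply(toks, function(r) {
    grp <- get(r, "group_PDB")
    if (!(grp == "ATOM" || (include_het && grp == "HETATM"))) return(NULL)
    data.frame(
      atom = gsub('"', "", get(r, "label_atom_id")),
      resname = get(r, "label_comp_id"),
      chain = get(r, "auth_asym_id") %||% get(r, "label_asym_id"),
      resno = as.integer(get(r, "auth_seq_id") %||% get(r, "label_seq_id")),
      x = as.numeric(get(r, "Cartn_x")),
      y = as.numeric(get(r, "Cartn_y")),
      z = as.numeric(get(r, "Cartn_z")),
      element = toupper(get(r, "type_symbol")))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) .nav_stop("no ATOM records",
                                            "navgate_io_error")
  out
}

#' @export
print.nav_structure <- function(x, ...) {
  cat(sprintf("<nav_structure> %d atoms, %d chains (%s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              basename(x$source)))
  invisible(x)
}
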