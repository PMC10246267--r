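#' Write / read a traceset in the package's plain-text trace format
#'
#' One TSV per sweep (`<stem>_sweep###.tsv`) with columns `time_ms`,
#' `v_mV`, `i_uA` and, when present, the simulated components
#' `i_ionic_uA`, `i_gating_uA`, `i_cap_uA`; plus a single JSON sidecar
#' (`<stem>.json`) carrying the recording metadata, per-sweep epoch
#' tables and swept variables. Numbers are written with `%.10g`, so a
#' write -> read -> write cycle is byte-identical.
#'
#' @param ts a `traceset` (from [propagate()] or [generate_recording()])
#' @param dir output directory (created if needed)
#' @param stem file-name stem (default the fixture or scheme name)
#' @return `write_traceset()` the sidecar path (invisibly);
#'   `read_traceset()` a `traceset`
#' @export
write_traceset <- function(ts, dir, stem = NULL) {
  stopifnot(inherits(ts, "traceset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% ts$meta$fixture %||% ts$meta$scheme %||% "traceset"
  files <- character(length(ts$sweeps))
  for (i in seq_along(ts$sweeps)) {
    tr <- ts$sweeps[[i]]$trace
    keep <- intersect(c("time_ms", "v_mV", "i_uA",
                        "i_ionic_uA", "i_gating_uA", "i_cap_uA"),
                      names(tr))
    tr <- tr[keep]
    files[i] <- sprintf("%s_sweep%03d.tsv", stem, i)
    con <- file(file.path(dir, files[i]), "wb")
    writeLines(paste(keep, collapse = "\t"), con)
    body <- do.call(paste, c(lapply(tr, function(col) sprintf("%.10g", col)),
                             sep = "\t"))
    writeLines(body, con)
    close(con)
  }
  side <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(schema = "navgate-traceset/1",
         meta = ts$meta,
         files = files,
         sweeps = lapply(ts$sweeps, function(s)
           list(epochs = s$epochs, info = s$info))),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}

#' @rdname write_traceset
#' @param sidecar path to the `<stem>.json` sidecar
#' @export
read_traceset <- function(sidecar) {
  x <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(x$schema) || !startsWith(x$schema, "navgate-traceset/"))
    .nav_stop("not a navgate traceset sidecar", "navgate_bad_traceset")
  dir <- dirname(sidecar)
  sweeps <- vector("list", length(x$files))
  for (i in seq_along(x$files)) {
    tr <- utils::read.table(file.path(dir, x$files[i]), header = TRUE,
                            sep = "\t", colClasses = "numeric")
    si <- if (is.data.frame(x$sweeps)) {
      list(epochs = x$sweeps$epochs[[i]], info = as.list(x$sweeps$info[i, ]))
    } else x$sweeps[[i]]
    sweeps[[i]] <- list(trace = tr,
                        epochs = as.data.frame(si$epochs),
                        info = as.list(si$info))
  }
  structure(list(sweeps = sweeps, meta = x$meta), class = "traceset")
}

# solution_pair back from traceset metadata
.ts_solution <- function(ts) {
  s <- ts$meta$sol
  solution_pair(s$na_out, s$k_out, s$na_in, s$k_in, s$temperature_K)
}

# per-sweep swept-variable, as a vector across sweeps
.ts_info <- function(ts, field) {
  vapply(ts$sweeps, function(s) {
    v <- s$info[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
}

# epoch lookup by role; returns row (with t0_ms/t1_ms) or NULL
.ts_epoch <- function(sweep, role) {
  e <- sweep$epochs
  i <- which(e$role == role)
  if (!length(i)) return(NULL)
  e[i[1], , drop = FALSE]
}
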