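#' Voltage-clamp protocols
#'
#' A protocol is an ordered family of sweeps, each a piecewise-constant
#' command-voltage waveform given as epochs `(v_mV, dur_ms, role)`.
#' Roles ("hold", "cond", "test", "depol", "tail", "off", "post") tag
#' which epoch downstream analyses should look at. `nav_protocol()` is
#' the low-level constructor; [protocol_builtin()] provides the named
#' families used throughout the package.
#'
#' @param sweeps list; each element is a list with `epochs`
#'   (data.frame `v_mV`, `dur_ms`, `role`) and `info` (named list of the
#'   swept variables for that sweep)
#' @param holding_mV holding potential the membrane sits at before t = 0
#' @param sample_ms sample interval (ms)
#' @param name protocol label
#' @return object of class `nav_protocol`
#' @export
nav_protocol <- function(sweeps, holding_mV = -130, sample_ms = 0.01,
                         name = "custom") {
  if (!length(sweeps)) .nav_stop("protocol has no sweeps", "navgate_bad_protocol")
  if (!is.finite(sample_ms) || sample_ms <= 0)
    .nav_stop("sample interval must be > 0", "navgate_bad_protocol")
  for (s in sweeps) {
    e <- s$epochs
    if (is.null(e) || !all(c("v_mV", "dur_ms") %in% names(e)))
      .nav_stop("each sweep needs epochs with v_mV, dur_ms",
                "navgate_bad_protocol")
    if (any(e$dur_ms <= 0)) .nav_stop("epoch durations must be > 0",
                                      "navgate_bad_protocol")
  }
  structure(list(sweeps = sweeps, holding_mV = holding_mV,
                 sample_ms = sample_ms, name = name),
            class = "nav_protocol")
}

#' @export
print.nav_protocol <- function(x, ...) {
  cat(sprintf("<nav_protocol> %s: %d sweeps, holding %g mV, dt %g ms\n",
              x$name, length(x$sweeps), x$holding_mV, x$sample_ms))
  invisible(x)
}

.epochs <- function(v, dur, role) data.frame(v_mV = v, dur_ms = dur,
                                             role = role,
                                             stringsAsFactors = FALSE)

#' Built-in protocol families
#'
#' * `"step"` - one depolarizing step with a tail back to holding.
#' * `"iv_family"` - 30 ms steps over a voltage family, for I-V / G-V.
#' * `"h_infinity"` - long conditioning at a voltage family followed by a
#'   fixed test pulse, for steady-state availability.
#' * `"immobilization_family"` - depolarizations of increasing duration
#'   followed by a return to the subtraction/holding voltage, for
#'   off-gating charge immobilization.
#' * `"instantaneous_iv"` - fixed-duration depolarizations followed by a
#'   family of tail voltages, repeated for several depolarization times.
#' * `"tail_duration_family"` - variable-duration depolarizations with a
#'   fixed hyperpolarized tail, for tail-kinetics vs duration.
#'
#' @param name one of the names above
#' @param holding_mV holding potential (mV)
#' @param sample_ms sample interval (ms)
#' @param test_mV,test_dur_ms step voltage and duration where applicable
#' @param family_mV voltage family (test or conditioning voltages)
#' @param durations_ms duration family where applicable
#' @param cond_dur_ms conditioning duration for `"h_infinity"`
#' @param tail_mV tail voltage for `"tail_duration_family"`
#' @param tail_family_mV tail-voltage family for `"instantaneous_iv"`
#' @param t_depol_ms depolarization times for `"instantaneous_iv"`
#' @param pre_ms settling time at holding before the first step
#' @return a [nav_protocol()]
#' @export
protocol_builtin <- function(name = c("step", "iv_family", "h_infinity",
                                      "immobilization_family",
                                      "instantaneous_iv",
                                      "tail_duration_family"),
                             holding_mV = -130, sample_ms = 0.01,
                             test_mV = 60, test_dur_ms = 30,
                             family_mV = seq(-80, 60, by = 10),
                             durations_ms = c(0.5, 1, 1.5, 2, 3, 5, 8, 12, 23),
                             cond_dur_ms = 200,
                             tail_mV = -80,
                             tail_family_mV = seq(-20, 60, by = 10),
                             t_depol_ms = c(0.6, 1, 2, 5, 10, 20),
                             pre_ms = 5) {
  name <- match.arg(name)
  hold <- function() .epochs(holding_mV, pre_ms, "hold")
  sweeps <- switch(
    name,
    step = list(list(
      epochs = rbind(hold(),
                     .epochs(test_mV, test_dur_ms, "test"),
                     .epochs(holding_mV, 10, "post")),
      info = list(test_mV = test_mV))),
    iv_family = lapply(family_mV, function(v) list(
      epochs = rbind(hold(),
                     .epochs(v, test_dur_ms, "test"),
                     .epochs(holding_mV, 10, "post")),
      info = list(test_mV = v))),
    h_infinity = lapply(family_mV, function(v) list(
      epochs = rbind(hold(),
                     .epochs(v, cond_dur_ms, "cond"),
                     .epochs(test_mV, test_dur_ms, "test"),
                     .epochs(holding_mV, 5, "post")),
      info = list(cond_mV = v, test_mV = test_mV))),
    immobilization_family = lapply(durations_ms, function(d) list(
      epochs = rbind(hold(),
                     .epochs(test_mV, d, "cond"),
                     .epochs(holding_mV, 30, "off")),
      info = list(dur_ms = d, test_mV = test_mV))),
    instantaneous_iv = {
      out <- list()
      for (td in t_depol_ms) for (vt in tail_family_mV)
        out[[length(out) + 1]] <- list(
          epochs = rbind(hold(),
                         .epochs(test_mV, td, "depol"),
                         .epochs(vt, 5, "tail"),
                         .epochs(holding_mV, 5, "post")),
          info = list(t_depol_ms = td, tail_mV = vt, test_mV = test_mV))
      out
    },
    tail_duration_family = lapply(durations_ms, function(d) list(
      epochs = rbind(hold(),
                     .epochs(test_mV, d, "depol"),
                     .epochs(tail_mV, 12, "tail"),
                     .epochs(holding_mV, 5, "post")),
      info = list(dur_ms = d, tail_mV = tail_mV, test_mV = test_mV)))
  )
  # defaults chosen for h_infinity: conditioning family reaches -10 mV
  if (name == "h_infinity" && identical(family_mV, seq(-80, 60, by = 10)))
    sweeps <- lapply(seq(-130, -10, by = 10), function(v) list(
      epochs = rbind(hold(),
                     .epochs(v, cond_dur_ms, "cond"),
                     .epochs(test_mV, test_dur_ms, "test"),
                     .epochs(holding_mV, 5, "post")),
      info = list(cond_mV = v, test_mV = test_mV)))
  nav_protocol(sweeps, holding_mV = holding_mV, sample_ms = sample_ms,
               name = name)
}

#' Read / write a protocol as JSON epoch lists
#'
#' @param path file path
#' @return `read_protocol()` a [nav_protocol()]; `write_protocol()` the
#'   path, invisibly
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema) || !startsWith(x$schema, "navgate-protocol/"))
    .nav_stop("not a navgate protocol file", "navgate_bad_protocol")
  sweeps <- lapply(seq_len(length(x$sweeps$epochs)), function(i)
    list(epochs = as.data.frame(x$sweeps$epochs[[i]]),
         info = as.list(x$sweeps$info[i, , drop = FALSE])))
  nav_protocol(sweeps, holding_mV = x$holding_mV,
               sample_ms = x$sample_ms, name = x$name)
}

#' @rdname read_protocol
#' @param protocol a [nav_protocol()]
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(
    list(schema = "navgate-protocol/1", name = protocol$name,
         holding_mV = protocol$holding_mV,
         sample_ms = protocol$sample_ms,
         sweeps = list(
           epochs = lapply(protocol$sweeps, `[[`, "epochs"),
           info = do.call(rbind, lapply(protocol$sweeps, function(s)
             as.data.frame(s$info))))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
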