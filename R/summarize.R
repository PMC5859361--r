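## Session summary: synchronized common-grid table, marker summary, phase
## table, a text report and a two-panel session figure.

#' Plot a session
#'
#' Two panels: water set temperature, perception rating and self-reported
#' shiver events (upper); the three skin-temperature channels (lower).
#'
#' @param x a [session_bundle()].
#' @param ... ignored.
#' @return the bundle, invisibly.
#' @export
plot.session_bundle <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))

  graphics::plot(x$water$time / 60, x$water$set_temp_c, type = "s",
                 col = "steelblue", lwd = 2, xlab = "time (min)",
                 ylab = "water temperature (degC)",
                 main = "Cooling protocol session")
  graphics::par(new = TRUE)
  graphics::plot(x$tgui$time / 60, x$tgui$slider, type = "l", col = "darkorange",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 100))
  graphics::axis(4)
  graphics::mtext("perception (0-100)", side = 4, line = 2.5, cex = 0.8)
  sh <- x$tgui[x$tgui$shiver == 1L, ]
  if (nrow(sh)) graphics::points(sh$time / 60, rep(5, nrow(sh)), pch = 16,
                                 cex = 0.5, col = "grey40")
  for (t in x$phases$start[x$phases$kind == "cooling"]) {
    graphics::abline(v = t / 60, col = "grey80", lty = 3)
  }

  graphics::matplot(x$skin$time / 60,
                    cbind(x$skin$clavicle_c, x$skin$forearm_c,
                          x$skin$finger_c),
                    type = "l", lty = 1, lwd = 1.5,
                    col = c("firebrick", "forestgreen", "grey40"),
                    xlab = "time (min)", ylab = "skin temperature (degC)")
  graphics::legend("bottomleft", c("clavicle", "forearm", "finger"),
                   col = c("firebrick", "forestgreen", "grey40"), lty = 1,
                   lwd = 1.5, bty = "n", cex = 0.8)
  invisible(x)
}

#' Summarize a session directory
#'
#' Reads a canonical session directory, resamples the streams onto a
#' common grid, extracts the physiological markers, and writes
#' `grid.csv`, `markers.csv`, `phases.csv`, a human-readable `report.txt`,
#' and a two-panel `summary.png`. The report is deterministic: running
#' twice on the same input produces byte-identical text outputs.
#'
#' @param session_dir directory holding canonical session logs (see
#'   [write_session()]).
#' @param out output directory (created if needed).
#' @param grid_step common-grid step, seconds.
#' @param figure whether to render `summary.png`.
#' @return invisibly, a list with the grid, markers, phases and the report
#'   lines.
#' @export
summarize_session <- function(session_dir, out, grid_step = 30,
                              figure = TRUE) {
  bundle <- read_session(session_dir)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  grid <- resample_common_grid(bundle, step = grid_step)
  markers <- detect_markers(bundle, grid_step = grid_step)
  utils::write.csv(grid, file.path(out, "grid.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(markers), file.path(out, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$phases), file.path(out, "phases.csv"),
                   row.names = FALSE)

  rep_lines <- c("Cooling protocol session summary",
                 "================================")
  ph <- bundle$phases
  tn <- which(ph$kind == "thermoneutral")
  if (length(tn)) {
    rep_lines <- c(rep_lines, sprintf("Thermoneutral water temperature: %g degC",
                                      ph$set_temp_c[tn[1L]]))
  }
  cool <- ph[ph$kind == "cooling", ]
  if (nrow(cool)) {
    rep_lines <- c(rep_lines,
                   sprintf("Cooling phases: %d (set temps %s degC)",
                           nrow(cool),
                           paste(cool$set_temp_c, collapse = ", ")),
                   sprintf("Shivering water temperature: %g degC",
                           cool$set_temp_c[nrow(cool)]))
  }
  rep_lines <- c(rep_lines, "", "Physiological markers:")
  for (i in seq_len(nrow(markers))) {
    m <- markers[i, ]
    rep_lines <- c(rep_lines, if (m$present) {
      sprintf("  %-22s t = %8.1f s, water %5.1f degC, perception %5.1f",
              m$marker, m$time, m$water_temp_c, m$perception)
    } else {
      sprintf("  %-22s absent", m$marker)
    })
  }
  if (is.null(bundle$emg)) {
    rep_lines <- c(rep_lines, "", "EMG: absent")
  } else {
    det <- detect_shiver(bundle$emg)
    rep_lines <- c(rep_lines, "",
                   sprintf("EMG: %d detected shiver event(s)",
                           nrow(det$events)))
  }
  writeLines(rep_lines, file.path(out, "report.txt"))

  if (figure) {
    grDevices::png(file.path(out, "summary.png"), width = 900, height = 700)
    plot(bundle)
    grDevices::dev.off()
  }
  invisible(list(grid = grid, markers = markers, phases = bundle$phases,
                 report = rep_lines))
}

#' Write a run manifest
#'
#' A JSON record written alongside every command-line output directory:
#' subcommand, a hash of the effective configuration, seed, input and
#' output paths, package version and timestamp. Identical manifests (minus
#' the timestamp) imply identical outputs for deterministic subcommands.
#'
#' @param out output directory.
#' @param subcommand character.
#' @param config list of effective parameter values.
#' @param seed integer or NULL.
#' @param inputs,outputs character vectors of paths.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(out, subcommand, config = list(), seed = NULL,
                           inputs = character(), outputs = character()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(subcommand = subcommand,
                   config_hash = .fnv1a(as.character(cfg_json)),
                   seed = seed, inputs = inputs, outputs = outputs,
                   package_version =
                     as.character(utils::packageVersion("coolprotocol")),
                   timestamp = format_iso_time(Sys.time()))
  path <- file.path(out, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## 32-bit FNV-1a over the UTF-8 bytes, returned as hex.
## h is kept as a double below 2^32; the xor only touches the low byte and
## the multiply by the FNV prime 16777619 = 2^24 + 403 is done modularly.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read a flat key=value configuration file
#'
#' Lines of `section.key=value`; blank lines and `#` comments ignored.
#' Values are converted to numeric where possible.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, trimws(vapply(kv, `[[`, "", 1L)))
}
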