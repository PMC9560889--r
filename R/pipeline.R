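# End-to-end workflow: configuration, the preprocess -> band extraction ->
# time-frequency causality -> summary chain, output bundle with manifest,
# and a small command-line front end.

#' Default pipeline configuration
#'
#' All tunables of the analysis chain in one validated list. Values mirror
#' the package defaults: 1-60 Hz bandpass, 250 Hz analysis rate, 3 s + 4 s
#' trial geometry, 7-level coif5 packets over 1-50 Hz, quadratic NARX with
#' p = q = 5 and a 10-term budget, 1 s windows advanced by 0.1 s.
#'
#' @param ... Named overrides of any top-level entry.
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    band = c(1, 60), target_fs = 250, pre_s = 3, post_s = 4,
    preprocess = FALSE, onsets = NULL,
    wavelet = "coif5", levels = 7L, freqs = 1:50,
    p = 5L, q = 5L, degree = 2L, rho = 0, n_max = 10L,
    window = 1, step = 0.1,
    bands = default_bands(), periods = default_periods(),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config entr", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "run_config"))
}

#' Validate a pipeline configuration against module preconditions
#' @param cfg A `run_config`.
#' @return The config, invisibly, or an error naming the offending entry.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  with(cfg, {
    if (!(band[1] > 0 && band[1] < band[2] && band[2] < target_fs / 2)) {
      stop("config band: need 0 < low < high < target_fs/2")
    }
    if (any(freqs <= 0 | freqs >= target_fs / 2)) {
      stop("config freqs: must lie in (0, target_fs/2)")
    }
    if (p < 1 || q < 0) stop("config p/q: need p >= 1, q >= 0")
    if (!degree %in% 1:2) stop("config degree: 1 or 2")
    if (window * target_fs < 10 * max(p, q) + 1) {
      stop("config window: ", window, " s too short at fs ", target_fs)
    }
  })
  invisible(cfg)
}

#' Run the full time-frequency causality pipeline
#'
#' Executes (optionally) the preprocessing chain, then per-band extraction
#' and sliding-window bidirectional GC, then band/period summaries, and
#' writes maps, summaries and a reproducibility manifest when `out_dir` is
#' given. Inputs may be numeric vectors or single-column CSV paths. When
#' `config$preprocess` is `FALSE` the inputs are taken as already
#' conditioned (they are z-normalized for scale safety, which does not
#' change GC).
#'
#' @param eeg,emg Numeric vectors or CSV file paths (single channel each).
#' @param config A `run_config` from [default_config()].
#' @param out_dir Optional output directory for the bundle.
#' @return A `pipeline_result`: both `tfgc_map`s, both band summaries, the
#'   config, and the file manifest (if written). The EEG series is the
#'   pipeline's `y`, the EMG series its `x`, so `xy` means EMG -> EEG and
#'   `yx` means EEG -> EMG.
#' @export
run_pipeline <- function(eeg, emg, config = default_config(), out_dir = NULL) {
  validate_config(config)
  load_one <- function(obj, label) {
    if (is.character(obj)) {
      rec <- read_delimited(obj, fs = config$target_fs)
      as.numeric(rec$samples[1L, ])
    } else as.numeric(obj)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  y <- stage("ingest eeg", load_one(eeg, "eeg"))
  x <- stage("ingest emg", load_one(emg, "emg"))
  if (length(x) != length(y)) stop("pipeline stage 'ingest': eeg and emg lengths differ")

  if (isTRUE(config$preprocess)) {
    if (is.null(config$onsets)) stop("pipeline stage 'preprocess': onsets required")
    seg <- stage("preprocess", {
      rec <- new_raw_recording(rbind(eeg = y, emg = x), fs = config$target_fs)
      preprocess_chain(rec, config$onsets, band = config$band,
                       target_fs = config$target_fs, pre_s = config$pre_s,
                       post_s = config$post_s, car = FALSE)
    })
    y <- as.numeric(seg$trials[["eeg"]][1L, ])
    x <- as.numeric(seg$trials[["emg"]][1L, ])
  } else {
    y <- as.numeric(scale(y))
    x <- as.numeric(scale(x))
  }

  maps <- stage("tf_gc_map", tf_gc_map(
    y, x, fs = config$target_fs, freqs = config$freqs,
    wavelet_name = config$wavelet, levels = config$levels,
    window = config$window, step = config$step,
    p = config$p, q = config$q, degree = config$degree,
    rho = config$rho, n_max = config$n_max
  ))
  # summarize only the bands/periods the computed map actually samples
  bands_used <- Filter(function(b) any(config$freqs >= b[1] & config$freqs < b[2]),
                       config$bands)
  periods_used <- Filter(function(p) any(maps$xy$times >= p[1] &
                                           maps$xy$times < p[2]),
                         config$periods)
  if (length(bands_used) == 0L || length(periods_used) == 0L) {
    stop("pipeline stage 'band_average': no configured band/period overlaps the map")
  }
  summaries <- stage("band_average", list(
    xy = band_average(maps$xy, bands_used, periods_used),
    yx = band_average(maps$yx, bands_used, periods_used)
  ))

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_map <- function(map, path) {
      df <- as.data.frame(map$values)
      utils::write.csv(cbind(frequency_hz = map$freqs, df), path,
                       row.names = FALSE)
    }
    files <- c(map_xy = "map_xy.csv", map_yx = "map_yx.csv",
               summary = "band_summary.csv", manifest = "manifest.json")
    write_map(maps$xy, file.path(out_dir, files[["map_xy"]]))
    write_map(maps$yx, file.path(out_dir, files[["map_yx"]]))
    utils::write.csv(rbind(summaries$xy, summaries$yx),
                     file.path(out_dir, files[["summary"]]), row.names = FALSE)
    manifest <- list(
      package = "wptgc",
      version = as.character(utils::packageVersion("wptgc")),
      config = config[setdiff(names(config), c("bands", "periods"))],
      bands = config$bands, periods = config$periods,
      n_samples = length(y),
      input_checksums = c(eeg = .vector_checksum(y), emg = .vector_checksum(x)),
      files = as.list(files)
    )
    jsonlite::write_json(manifest, file.path(out_dir, files[["manifest"]]),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(maps = maps, summaries = summaries, config = config,
         manifest = manifest, out_dir = out_dir),
    class = "pipeline_result"
  )
}

# Order-dependent checksum of a numeric vector (FNV-style over a coarse
# digit string); enough to certify two bundles saw identical input.
.vector_checksum <- function(v) {
  s <- paste(sprintf("%.12e", v), collapse = ",")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- bitwAnd((h * 16777619) %% 2^31, 2^31 - 1) + ch %% 7
  sprintf("%08x", as.integer(h %% 2^31))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$maps$xy); print(x$maps$yx)
  if (!is.null(x$out_dir)) cat("  bundle written to", x$out_dir, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Command-line front end. Subcommands: simulate, decompose, gc, tfmap,
# bands, stats, run. Flags are --key value pairs; see each handler.

.cli_parse <- function(args) {
  flags <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        flags[[key]] <- TRUE; i <- i + 1L
      } else {
        flags[[key]] <- args[[i + 1L]]; i <- i + 2L
      }
    } else {
      positional <- c(positional, a); i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

.cli_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

.cli_range <- function(spec) {
  # "1:50" or "4,12,20"
  if (grepl(":", spec, fixed = TRUE)) {
    parts <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1L]])
    seq(parts[1], parts[2])
  } else as.numeric(strsplit(spec, ",", fixed = TRUE)[[1L]])
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `decompose`, `gc`, `tfmap`, `bands`, `stats` and
#' `run` subcommands; see the package README for flag summaries. Intended
#' to be called from an Rscript wrapper (one is installed under
#' `exec/wptgc`).
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the subcommand's result object.
#' @export
wptgc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: wptgc <simulate|decompose|gc|tfmap|bands|stats|run> [--flags]\n")
    return(invisible(NULL))
  }
  cmd <- args[[1L]]
  pa <- .cli_parse(args[-1L])
  fl <- pa$flags; pos <- pa$positional
  res <- switch(
    cmd,
    simulate = {
      name <- fl$fixture %||% "linear_unidirectional"
      sim <- simulate_fixture(name,
                              n = if (is.null(fl$n)) NULL else as.integer(fl$n),
                              seed = if (is.null(fl$seed)) NULL else as.integer(fl$seed))
      if (length(pos) >= 2L) {
        utils::write.csv(data.frame(x = sim$x), pos[[1L]], row.names = FALSE)
        utils::write.csv(data.frame(y = sim$y), pos[[2L]], row.names = FALSE)
        if (length(pos) >= 3L) {
          jsonlite::write_json(sim$truth, pos[[3L]], auto_unbox = TRUE,
                               digits = NA, pretty = TRUE)
        }
      }
      sim
    },
    decompose = {
      if (length(pos) < 2L) stop("decompose needs: in.csv out_dir")
      fs <- .cli_num(fl, "fs", 250)
      rec <- read_delimited(pos[[1L]], fs = fs)
      d <- wpt_decompose(rec$samples[1L, ], fl$wavelet %||% "coif5",
                         as.integer(.cli_num(fl, "levels", 7)), fs)
      freqs <- .cli_range(fl$bands %||% "1:50")
      dir.create(pos[[2L]], recursive = TRUE, showWarnings = FALSE)
      manifest <- lapply(freqs, function(f) {
        b <- extract_band(d, f)
        utils::write.csv(data.frame(w = b$w),
                         file.path(pos[[2L]], sprintf("band_%ghz.csv", f)),
                         row.names = FALSE)
        list(f_center = f, f_lo = b$band[["f_lo"]], f_hi = b$band[["f_hi"]])
      })
      jsonlite::write_json(manifest, file.path(pos[[2L]], "bands.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      invisible(manifest)
    },
    gc = {
      if (length(pos) < 2L) stop("gc needs: y.csv x.csv")
      fs <- .cli_num(fl, "fs", 250)
      yv <- read_delimited(pos[[1L]], fs = fs)$samples[1L, ]
      xv <- read_delimited(pos[[2L]], fs = fs)$samples[1L, ]
      gp <- gc_pair(yv, xv, p = as.integer(.cli_num(fl, "p", 5)),
                    q = as.integer(.cli_num(fl, "q", 5)),
                    rho = .cli_num(fl, "rho", 0),
                    n_max = as.integer(.cli_num(fl, "nmax", 10)))
      print(gp)
      gp
    },
    tfmap = ,
    run = {
      if (length(pos) < 2L) stop(cmd, " needs: eeg.csv emg.csv [out_dir]")
      cfg <- default_config(
        target_fs = .cli_num(fl, "fs", 250),
        freqs = .cli_range(fl$freqs %||% "1:50"),
        window = .cli_num(fl, "window", 1),
        step = .cli_num(fl, "step", 0.1),
        seed = as.integer(.cli_num(fl, "seed", 1))
      )
      out <- if (length(pos) >= 3L) pos[[3L]] else NULL
      pr <- run_pipeline(pos[[1L]], pos[[2L]], cfg, out_dir = out)
      print(pr)
      pr
    },
    bands = {
      if (length(pos) < 1L) stop("bands needs: map.csv")
      df <- utils::read.csv(pos[[1L]], check.names = FALSE)
      freqs <- df[[1L]]
      vals <- as.matrix(df[, -1L, drop = FALSE])
      times <- as.numeric(sub("s$", "", sub("^X?", "", colnames(vals))))
      map <- structure(list(freqs = freqs, times = times, values = vals,
                            direction = "X->Y", failed_bands = character(0)),
                       class = "tfgc_map")
      ba <- band_average(map)
      print(ba)
      ba
    },
    stats = {
      if (length(pos) < 1L) stop("stats needs: groups.csv (columns = groups)")
      df <- utils::read.csv(pos[[1L]], check.names = FALSE)
      gt <- compare_groups(as.list(df))
      print(gt)
      gt
    },
    stop("unknown subcommand '", cmd, "'")
  )
  invisible(res)
}
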