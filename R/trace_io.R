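#' Write intensity traces with a dataset manifest
#'
#' Writes one tab-separated file per molecule (columns `frame`, `time_s`,
#' `donor`, `acceptor`), a JSON manifest describing the dataset (construct
#' fields, frame rate, seed, file paths), and optional per-trace ground
#' truth as JSON.
#'
#' @param traces List of [intensity_trace()] objects.
#' @param dir Output directory (created if missing).
#' @param construct A [construct_spec()] or construct name recorded in the
#'   manifest.
#' @param frame_rate Frame rate recorded in the manifest, Hz.
#' @param seed Seed recorded in the manifest (may be `NULL`).
#' @param truths Optional list of ground-truth lists, same length as
#'   `traces`.
#' @return Invisibly, the manifest file path.
#' @export
write_traces <- function(traces, dir, construct = NULL, frame_rate = NULL,
                         seed = NULL, truths = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(frame_rate)) frame_rate <- traces[[1]]$frame_rate
  files <- character(length(traces))
  truth_files <- if (is.null(truths)) NULL else character(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "intensity_trace"))
    files[i] <- sprintf("trace_%04d.tsv", i)
    utils::write.table(
      data.frame(frame = tr$frame, time_s = tr$time_s,
                 donor = tr$donor, acceptor = tr$acceptor),
      file.path(dir, files[i]),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    if (!is.null(truths)) {
      truth_files[i] <- sprintf("trace_%04d.truth.json", i)
      jsonlite::write_json(truths[[i]], file.path(dir, truth_files[i]),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  cs <- if (inherits(construct, "construct_spec")) {
    unclass(construct)
  } else {
    list(name = construct)
  }
  manifest <- list(
    construct = cs, frame_rate = frame_rate, seed = seed,
    trace_files = files, truth_files = truth_files
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest_path)
}

#' Read intensity traces described by a dataset manifest
#'
#' @param dir Dataset directory containing the manifest and trace files.
#' @param manifest Manifest file name within `dir`.
#' @return A list with `traces` (list of [intensity_trace()]), `truths`
#'   (list of ground-truth lists or `NULL`), and `construct` (the manifest's
#'   construct fields).
#' @export
read_traces <- function(dir, manifest = "manifest.json") {
  mpath <- file.path(dir, manifest)
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  frame_rate <- m$frame_rate
  cname <- m$construct$name
  traces <- vector("list", length(m$trace_files))
  for (i in seq_along(m$trace_files)) {
    path <- file.path(dir, m$trace_files[i])
    if (!file.exists(path)) stop("trace file listed in manifest is missing: ", path)
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t"),
      error = function(e) stop("malformed trace file ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    need <- c("frame", "donor", "acceptor")
    if (!all(need %in% names(df))) {
      stop("trace file ", path, " lacks required columns ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    if (anyNA(df$donor) || anyNA(df$acceptor) ||
        length(df$donor) != length(df$acceptor)) {
      stop("trace file ", path, " has missing values or unequal channel lengths")
    }
    traces[[i]] <- intensity_trace(df$donor, df$acceptor, frame_rate, cname)
  }
  truths <- NULL
  if (!is.null(m$truth_files) && !all(is.na(m$truth_files))) {
    truths <- lapply(file.path(dir, m$truth_files), function(p) {
      jsonlite::read_json(p, simplifyVector = TRUE)
    })
  }
  list(traces = traces, truths = truths, construct = m$construct)
}
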