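#' Reading and writing pipeline inputs and outputs
#'
#' All interchange formats are plain delimited text: TSV/CSV time series
#' (T rows x N columns, optional header of node ids), a TSV parcellation
#' (node_id, label, subnetwork), a CSV cohort manifest
#' (subject_id, sex, age, education, mean_fd, run1..runk paths), and
#' long-form TSV metric tables. Writers store full double precision so
#' every writer/reader pair is an identity on valid data.
#'
#' @name io
NULL

.sniffSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

# format a double so that read-back is bit-identical
.fmtNum <- function(x) formatC(x, digits = 17, format = "g", width = 1)

#' Read an ROI time-series file
#'
#' Reads a delimited (TSV or CSV, sniffed from the first line) numeric
#' matrix of T timepoints x N nodes. A non-numeric first row is treated as
#' a header of node ids. Validation failures name the offending row or
#' column.
#'
#' @param path file path.
#' @param trSeconds repetition time in seconds.
#' @param subjectId,runId identifiers to attach.
#' @return A \linkS4class{RoiTimeSeries}.
#' @export
readTimeSeries <- function(path, trSeconds, subjectId = "s1", runId = "r1") {
  sep <- .sniffSep(path)
  nf <- utils::count.fields(path, sep = sep, blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged rows: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]))
  }
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  hasHeader <- anyNA(suppressWarnings(as.numeric(first)))
  raw <- utils::read.table(path, sep = sep, header = hasHeader,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, column %d", bad[1L], bad[2L]))
  }
  m <- matrix(as.numeric(m), nrow = nrow(raw),
              dimnames = list(NULL, if (hasHeader) names(raw) else NULL))
  roiTimeSeries(m, trSeconds, subjectId, runId)
}

#' Write an ROI time-series file
#'
#' TSV with a header row of node ids and full double precision.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "RoiTimeSeries"))
  x <- ts@data
  chr <- apply(x, 2L, .fmtNum)
  lines <- c(paste(colnames(x), collapse = "\t"),
             apply(chr, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parcellation table
#'
#' TSV with columns \code{node_id}, \code{label}, \code{subnetwork}.
#' Subnetwork names must come from the declared set (by default the nine
#' canonical subsystems); pass \code{subnetworkSet} to declare a custom
#' set.
#'
#' @param path file path.
#' @param subnetworkSet declared subnetwork names; default
#'   \code{\link{defaultSubnetworks}()}.
#' @return A \linkS4class{Parcellation}.
#' @export
readParcellation <- function(path, subnetworkSet = defaultSubnetworks()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("node_id", "label", "subnetwork")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("parcellation file lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  parcellation(df$node_id, df$subnetwork, nodeLabels = df$label,
               subnetworkSet = subnetworkSet)
}

#' Write a parcellation table
#'
#' @param parc a \linkS4class{Parcellation}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeParcellation <- function(parc, path) {
  stopifnot(is(parc, "Parcellation"))
  df <- data.frame(node_id = parc@nodeIds, label = parc@nodeLabels,
                   subnetwork = parc@subnetwork, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.metricCols <- c("subject", "run", "density", "scope", "metric", "value")

#' Write a metric table
#'
#' Long-form TSV with the stable column order subject, run, density,
#' scope, metric, value and full float precision; an empty table yields a
#' header-only file.
#'
#' @param table metric table data.frame.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeMetricTable <- function(table, path) {
  stopifnot(all(.metricCols %in% names(table)))
  out <- table[, .metricCols, drop = FALSE]
  out$density <- .fmtNum(out$density)
  out$value <- .fmtNum(out$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metric table
#'
#' @param path TSV written by \code{\link{writeMetricTable}}.
#' @return metric table data.frame.
#' @export
readMetricTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(subject = "character",
                                         run = "character",
                                         density = "numeric",
                                         scope = "character",
                                         metric = "character",
                                         value = "numeric"))
  df[, .metricCols, drop = FALSE]
}

# write cohort + runs + parcellation + ground truth under dir
.writeCohortFiles <- function(coh, parc, truth, spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeParcellation(parc, file.path(dir, "parcellation.tsv"))
  s <- subjectTable(coh)
  k <- nRuns(coh)
  runPaths <- matrix("", nrow(s), k)
  for (i in seq_len(nrow(s))) {
    rl <- runsOf(coh, s$subjectId[i])
    for (r in seq_len(k)) {
      fn <- sprintf("%s_%s.tsv", s$subjectId[i], runId(rl[[r]]))
      writeTimeSeries(rl[[r]], file.path(dir, fn))
      runPaths[i, r] <- fn
    }
  }
  manifest <- data.frame(subject_id = s$subjectId,
                         sex = as.character(s$sex),
                         age = .fmtNum(s$age),
                         education = .fmtNum(s$education),
                         mean_fd = .fmtNum(s$meanFd),
                         stringsAsFactors = FALSE)
  for (r in seq_len(k)) manifest[[paste0("run", r)]] <- runPaths[, r]
  utils::write.table(manifest, file.path(dir, "cohort.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(parameters = list(
           nSubjects = spec@nSubjects, kRuns = spec@kRuns,
           nNodes = spec@nNodes, tPoints = spec@tPoints,
           trSeconds = spec@trSeconds, baseDwell = spec@baseDwell,
           sexEffect = spec@sexEffect, ageSlope = spec@ageSlope,
           sigmaSubject = spec@sigmaSubject, sigmaRun = spec@sigmaRun,
           noiseSd = spec@noiseSd, seed = spec@seed),
         truth = truth,
         version = as.character(utils::packageVersion("temponet"))),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort manifest and its runs
#'
#' Reads the CSV manifest (subject_id, sex, age, education, mean_fd,
#' run1..runk) and loads every referenced time-series file (paths relative
#' to the manifest's directory).
#'
#' @param path manifest CSV path.
#' @param trSeconds repetition time of the runs.
#' @return A \linkS4class{Cohort}.
#' @export
readCohort <- function(path, trSeconds) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE)
  runCols <- grep("^run[0-9]+$", names(df), value = TRUE)
  if (!length(runCols)) stop("cohort manifest has no run columns")
  base <- dirname(path)
  runs <- vector("list", nrow(df))
  names(runs) <- df$subject_id
  for (i in seq_len(nrow(df))) {
    runs[[i]] <- lapply(runCols, function(rc) {
      readTimeSeries(file.path(base, df[[rc]][i]), trSeconds,
                     subjectId = df$subject_id[i],
                     runId = sub("^run", "run", rc))
    })
  }
  subjects <- data.frame(subjectId = df$subject_id, sex = df$sex,
                         age = df$age, education = df$education,
                         meanFd = df$mean_fd, stringsAsFactors = FALSE)
  cohort(subjects, runs)
}

#' Write a JSON sidecar with run parameters
#'
#' Records analysis parameters, seed and package version next to an output
#' table so results stay traceable.
#'
#' @param path destination .json path.
#' @param parameters named list of analysis parameters.
#' @param seed integer seed used (or NULL).
#' @return \code{path}, invisibly.
#' @export
writeRunMetadata <- function(path, parameters, seed = NULL) {
  jsonlite::write_json(
    list(parameters = parameters, seed = seed,
         version = as.character(utils::packageVersion("temponet")),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
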