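.tacColumns <- c(
  "frame_start_s", "frame_duration_s", "blood", "global", "lad", "lcx", "rca"
)

#' Read and write the per-study TAC file format
#'
#' One CSV per patient, state and modality, with header
#' `frame_start_s,frame_duration_s,blood,global,lad,lcx,rca`: the frame grid
#' in seconds followed by frame-averaged activity (kBq/mL) for the blood
#' pool, the global left ventricle and the three coronary territories.
#' Frames must be contiguous with positive durations; unknown extra columns
#' are accepted with a warning, missing ones are an error naming the column.
#'
#' @param path CSV file path.
#' @return `readTacFile()` returns a named list of five
#'   [TimeActivityCurve-class] objects (`blood`, `global`, `lad`, `lcx`,
#'   `rca`) sharing one schedule; `writeTacFile()` writes such a list and
#'   returns `path` invisibly.
#' @export
readTacFile <- function(path) {
  if (!file.exists(path)) stop("TAC file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(.tacColumns, colnames(df))
  if (length(miss) > 0) {
    stop(
      "TAC file ", path, " is missing column(s): ",
      paste(miss, collapse = ", ")
    )
  }
  extra <- setdiff(colnames(df), .tacColumns)
  if (length(extra) > 0) {
    warning(
      "TAC file ", path, " has unknown column(s), ignored: ",
      paste(extra, collapse = ", ")
    )
  }
  s <- df$frame_start_s
  d <- df$frame_duration_s
  if (any(d <= 0)) {
    stop(
      "TAC file ", path, ": non-positive frame_duration_s at row ",
      which(d <= 0)[1L]
    )
  }
  if (nrow(df) > 1L) {
    gap <- s[-1L] - (s[-nrow(df)] + d[-nrow(df)])
    bad <- which(abs(gap) > 1e-9)
    if (length(bad) > 0) {
      stop(
        "TAC file ", path, ": frames not contiguous at row ", bad[1L] + 1L,
        " (frame_start_s = ", s[bad[1L] + 1L], ", expected ",
        s[bad[1L]] + d[bad[1L]], ")"
      )
    }
  }
  sched <- FrameSchedule(frameStart = s, frameDuration = d)
  labels <- c(
    blood = "BLOOD", global = "GLOBAL", lad = "LAD", lcx = "LCX", rca = "RCA"
  )
  out <- lapply(names(labels), function(col) {
    v <- df[[col]]
    if (anyNA(v) || any(!is.finite(v))) {
      stop(
        "TAC file ", path, ": non-finite value in column '", col,
        "' at row ", which(!is.finite(v))[1L]
      )
    }
    TimeActivityCurve(sched, pmax(v, 0), label = labels[[col]])
  })
  names(out) <- names(labels)
  out
}

#' @param tacs named list of five [TimeActivityCurve-class] objects
#'   (`blood`, `global`, `lad`, `lcx`, `rca`) on a common schedule.
#' @rdname readTacFile
#' @export
writeTacFile <- function(tacs, path) {
  .checkTacSet(tacs, "write")
  sched <- tacSchedule(tacs$blood)
  df <- data.frame(
    frame_start_s = frameStart(sched),
    frame_duration_s = frameDuration(sched),
    blood = tacValues(tacs$blood),
    global = tacValues(tacs$global),
    lad = tacValues(tacs$lad),
    lcx = tacValues(tacs$lcx),
    rca = tacValues(tacs$rca)
  )
  # %.17g round-trips doubles exactly through the CSV
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# SimConfig <-> plain list, for the JSON copy written next to the cohort
.simConfigAsList <- function(config) {
  nm <- slotNames("SimConfig")
  out <- lapply(nm, function(s) slot(config, s))
  names(out) <- nm
  out
}

#' Write a simulated cohort to disk
#'
#' Materializes a [simulateStudy()] result as the package's file interface:
#' one TAC CSV per patient, state and modality
#' (`P{ID}_{rest|stress}_{spect|pet}.csv`), the ground-truth table
#' `truth.csv`, the FFR table `ffr.csv` (`patient_id`, `territory`, `ffr`)
#' and a JSON copy of the generator configuration (`sim_config.json`).
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(all(c("patients", "truth", "config") %in% names(study)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pat in study$patients) {
    for (modality in c("spect", "pet")) {
      for (state in c("rest", "stress")) {
        writeTacFile(
          pat[[modality]][[state]],
          file.path(dir, sprintf("%s_%s_%s.csv", pat$id, state, modality))
        )
      }
    }
  }
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
    row.names = FALSE, quote = FALSE
  )
  utils::write.csv(
    study$truth[, c("patient_id", "territory", "ffr")],
    file.path(dir, "ffr.csv"),
    row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    .simConfigAsList(study$config),
    file.path(dir, "sim_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Run the full analysis pipeline over a study directory
#'
#' End-to-end driver: discovers patients in `inputDir` (files written by
#' [writeStudy()] or following the same naming scheme), quantifies every
#' patient with both arms ([quantifySpect()] on the sestamibi files,
#' [quantifyPet()] on the water files), reads `ffr.csv`, and assembles the
#' diagnostic [concordanceReport()]. Per-patient failures are collected in a
#' manifest and do not abort the run; warnings raised during quantification
#' (clamped retention rates, non-converged fits) are recorded per patient.
#'
#' @param inputDir directory holding `P*_{rest,stress}_{spect,pet}.csv` and
#'   `ffr.csv`.
#' @param outDir optional output directory; if given, `report.json` and
#'   per-patient flow JSONs are written there.
#' @param retention a [RetentionParams-class].
#' @param water a [WaterModelParams-class].
#' @param thresholds a [FlowThresholds-class].
#' @return list: `report` (the concordance report), `spect` and `pet`
#'   (per-patient flow data.frames), `failures` and `warnings` manifests.
#' @export
runPipeline <- function(inputDir, outDir = NULL,
                        retention = retentionParams(),
                        water = waterModelParams(),
                        thresholds = flowThresholds()) {
  if (!dir.exists(inputDir)) stop("input directory not found: ", inputDir)
  restSpect <- list.files(inputDir, pattern = "_rest_spect\\.csv$")
  ids <- sort(sub("_rest_spect\\.csv$", "", restSpect))
  if (length(ids) == 0) stop("no patients found in ", inputDir)
  ffrPath <- file.path(inputDir, "ffr.csv")
  if (!file.exists(ffrPath)) stop("missing FFR table: ", ffrPath)
  ffrTable <- utils::read.csv(ffrPath)

  spectAll <- NULL
  petAll <- NULL
  failures <- list()
  warnLog <- list()
  for (id in ids) {
    res <- withCallingHandlers(
      tryCatch(
        {
          readState <- function(state, modality) {
            readTacFile(file.path(
              inputDir, sprintf("%s_%s_%s.csv", id, state, modality)
            ))
          }
          s <- quantifySpect(
            readState("rest", "spect"), readState("stress", "spect"),
            retention
          )
          p <- quantifyPet(
            readState("rest", "pet"), readState("stress", "pet"), water
          )
          list(spect = s, pet = p)
        },
        error = function(e) conditionMessage(e)
      ),
      warning = function(w) {
        warnLog[[id]] <<- c(warnLog[[id]], conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    if (is.character(res)) {
      failures[[id]] <- res
      next
    }
    res$spect$patient_id <- id
    res$pet$patient_id <- id
    spectAll <- rbind(spectAll, res$spect)
    petAll <- rbind(petAll, res$pet)
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      jsonlite::write_json(
        list(spect = res$spect, pet = res$pet),
        file.path(outDir, sprintf("%s_flows.json", id)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
  }
  if (is.null(spectAll)) {
    stop(
      "all patients failed; first failure: ", ids[1L], ": ",
      failures[[ids[1L]]]
    )
  }
  ok <- ffrTable$patient_id %in% spectAll$patient_id
  report <- concordanceReport(
    spectAll, petAll, ffrTable[ok, , drop = FALSE], thresholds
  )
  out <- list(
    report = report, spect = spectAll, pet = petAll,
    failures = failures, warnings = warnLog
  )
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    jsonlite::write_json(
      list(report = report, failures = failures, warnings = warnLog),
      file.path(outDir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}
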