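# Interchange formats: curves as CSV (time_s + one column per curve), maps as
# NIfTI (plain-text matrix fallback), contours as JSON, cohorts as CSV.
# All writers go through a temp file renamed on success, so a failure never
# leaves a partially written output.

write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop_invalid("could not move temporary file onto %s", path)
  invisible(path)
}

#' Write/read dynamic curves as CSV
#'
#' Wide format: a `time_s` column, an `aif` column, and one `px_<x>_<y>`
#' column per masked pixel (0-based pixel indices, `which(mask)` order).
#'
#' @param times frame times, seconds.
#' @param aif AIF curve.
#' @param tissue matrix of tissue curves (one column per pixel), or NULL.
#' @param mask logical matrix locating the pixel columns, or NULL for
#'   anonymous `curve_<i>` names.
#' @param path output CSV path.
#' @return `path`, invisibly (writer); a list with `times`, `aif`, `tissue`,
#'   `pixel_index` (reader).
#' @export
write_curves <- function(path, times, aif, tissue = NULL, mask = NULL) {
  df <- data.frame(time_s = times, aif = aif)
  if (!is.null(tissue)) {
    tissue <- as.matrix(tissue)
    nm <- if (!is.null(mask)) {
      idx <- which(as.matrix(mask), arr.ind = TRUE)
      sprintf("px_%d_%d", idx[, 1] - 1L, idx[, 2] - 1L)
    } else sprintf("curve_%d", seq_len(ncol(tissue)))
    colnames(tissue) <- nm
    df <- cbind(df, tissue)
  }
  write_atomic(path, function(tmp) {
    if (!is.null(mask))
      writeLines(sprintf("# grid %d %d", nrow(mask), ncol(mask)), tmp)
    suppressWarnings(utils::write.table(df, tmp, sep = ",", dec = ".",
                                        row.names = FALSE, append = !is.null(mask)))
  })
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  first <- readLines(path, n = 1)
  grid_dim <- NULL
  if (grepl("^# grid ", first))
    grid_dim <- as.integer(strsplit(sub("^# grid ", "", first), " ")[[1]])
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  for (col in c("time_s", "aif"))
    if (!col %in% names(df))
      stop_invalid("%s: curves file is missing the '%s' column", path, col)
  px <- grep("^(px_|curve_)", names(df), value = TRUE)
  pixel_index <- NULL
  if (length(px) && all(startsWith(px, "px_"))) {
    parts <- do.call(rbind, strsplit(sub("^px_", "", px), "_"))
    pixel_index <- cbind(x = as.integer(parts[, 1]), y = as.integer(parts[, 2]))
  }
  list(times = df$time_s, aif = df$aif,
       tissue = if (length(px)) as.matrix(df[px]) else NULL,
       pixel_index = pixel_index, grid_dim = grid_dim)
}

#' Write/read an MBF map
#'
#' NIfTI (via the RNifti reader/writer, 32-bit float, `.nii`/`.nii.gz`) or a
#' whitespace-delimited plain-text matrix (any other extension); unmasked
#' pixels are stored as NaN and recovered into the mask on read.
#'
#' @param map an [mbf_map()].
#' @param path destination; extension selects the format.
#' @param state map state used when reading (`"stress"`/`"rest"`).
#' @return `path` invisibly (writer); an `mbf_map` (reader).
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "mbf_map"))
  v <- map$values
  v[!map$mask] <- NaN
  write_atomic(path, function(tmp) {
    if (grepl("\\.nii(\\.gz)?$", path)) {
      RNifti::writeNifti(RNifti::asNifti(v), tmp, datatype = "float")
    } else {
      utils::write.table(v, tmp, row.names = FALSE, col.names = FALSE)
    }
  })
}

#' @rdname write_map
#' @export
read_map <- function(path, state = c("stress", "rest")) {
  state <- match.arg(state)
  v <- if (grepl("\\.nii(\\.gz)?$", path)) {
    as.matrix(RNifti::readNifti(path))
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  dimnames(v) <- NULL
  mask <- is.finite(v)
  v[!mask] <- NA_real_
  mbf_map(v, mask, state = state)
}

#' Write/read a contour set as JSON
#'
#' Schema: `{slice, endo: [[x,y],...], epi: [[x,y],...], rv_insertion: [x,y]}`.
#'
#' @param contours a [contour_set()].
#' @param path JSON path.
#' @return `path` invisibly (writer); a `contour_set` (reader).
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  obj <- list(slice = contours$slice_level,
              endo = unname(contours$endo), epi = unname(contours$epi),
              rv_insertion = contours$rv_insertion)
  write_atomic(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("slice", "endo", "epi", "rv_insertion"))
    if (is.null(obj[[f]]))
      stop_invalid("%s: contours file is missing field '%s'", path, f)
  contour_set(obj$slice, as.matrix(obj$endo), as.matrix(obj$epi),
              as.numeric(obj$rv_insertion))
}

cohort_required_cols <- c(
  "id", "rhythm", "age", "sex", "lvef", "lge", "beta_blocker", "agent",
  "rest_hr", "rest_sbp", "rest_dbp", "stress_hr", "stress_sbp", "stress_dbp",
  "splenic_switch_off", "stress_mbf", "rest_mbf", "indexed_lv_mass")

#' Write/read a cohort table as CSV
#'
#' Column dictionary: `id`; `rhythm` (sinus/af); `age` (years); `sex`
#' (female/male); `lvef` (%); `lge` (none/ischemic/non_ischemic/mixed);
#' `beta_blocker` (logical); `agent` (adenosine/regadenoson);
#' `adenosine_dose` (ug/kg/min, NA for regadenoson); `rest_hr`/`stress_hr`
#' (bpm); `rest_sbp`/`rest_dbp`/`stress_sbp`/`stress_dbp` (mmHg);
#' `splenic_switch_off` (logical, NA when not assessable);
#' `stress_mbf`/`rest_mbf` and the endo/epi variants (mL/min/g, rest values
#' NA when rest imaging is absent); `indexed_lv_mass` (g/m2).
#'
#' @param cohort cohort data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); validated data frame (reader).
#' @export
write_cohort <- function(cohort, path) {
  write_atomic(path, function(tmp)
    utils::write.csv(cohort, tmp, row.names = FALSE))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols))
    stop_invalid("%s: cohort file is missing required columns: %s", path,
                 paste(missing_cols, collapse = ", "))
  df
}

# ---- study bundle ----------------------------------------------------------

#' Write/read a per-patient study bundle
#'
#' A study bundle holds, per state (stress/rest), up to three short-axis
#' slices (each an MBF map plus its contours, optionally the dynamic curves),
#' the vital signs, and one cohort metadata row. On disk it is a directory:
#' `meta.csv`, then `<state>/vitals.json`, `<state>/<level>_map.nii.gz`,
#' `<state>/<level>_contours.json` and optional `<state>/<level>_curves.csv`.
#'
#' @param bundle list with `meta` (one-row data frame) and `states`, a named
#'   list (`stress`, `rest`) of lists with `vitals` (named numeric `hr`,
#'   `sbp`, `dbp`) and `slices` (named by level: list with `map`, `contours`,
#'   optional `curves = list(times, aif, tissue)`).
#' @param dir bundle directory.
#' @return `dir` invisibly (writer); a bundle list (reader).
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic(file.path(dir, "meta.csv"), function(tmp)
    utils::write.csv(bundle$meta, tmp, row.names = FALSE))
  for (state in names(bundle$states)) {
    st <- bundle$states[[state]]
    sdir <- file.path(dir, state)
    dir.create(sdir, showWarnings = FALSE)
    if (anyDuplicated(names(st$slices)))
      stop_invalid("slice levels must be unique within a state")
    write_atomic(file.path(sdir, "vitals.json"), function(tmp)
      jsonlite::write_json(as.list(st$vitals), tmp, auto_unbox = TRUE,
                           digits = NA))
    for (level in names(st$slices)) {
      sl <- st$slices[[level]]
      write_map(sl$map, file.path(sdir, paste0(level, "_map.nii.gz")))
      write_contours(sl$contours,
                     file.path(sdir, paste0(level, "_contours.json")))
      if (!is.null(sl$curves))
        write_curves(file.path(sdir, paste0(level, "_curves.csv")),
                     sl$curves$times, sl$curves$aif, sl$curves$tissue)
    }
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  states <- list()
  for (state in intersect(c("stress", "rest"), list.dirs(dir, full.names = FALSE))) {
    sdir <- file.path(dir, state)
    vit <- unlist(jsonlite::read_json(file.path(sdir, "vitals.json"),
                                      simplifyVector = TRUE))
    slices <- list()
    for (f in list.files(sdir, pattern = "_map\\.nii\\.gz$")) {
      level <- sub("_map\\.nii\\.gz$", "", f)
      sl <- list(
        map = read_map(file.path(sdir, f), state = state),
        contours = read_contours(file.path(sdir, paste0(level, "_contours.json"))))
      cf <- file.path(sdir, paste0(level, "_curves.csv"))
      if (file.exists(cf)) {
        cc <- read_curves(cf)
        sl$curves <- list(times = cc$times, aif = cc$aif, tissue = cc$tissue)
      }
      slices[[level]] <- sl
    }
    states[[state]] <- list(vitals = vit, slices = slices)
  }
  list(meta = meta, states = states)
}
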