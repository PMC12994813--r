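# File I/O and configuration: NIfTI volume pairs, versioned cohort CSV,
# JSON configuration round-trips, and a reproducibility manifest.

COHORT_SCHEMA <- "hushift_cohort_v1"

#' Analysis configuration
#'
#' Houses the pipeline's fixed clinical/imaging constants: the percentile
#' threshold (-250 HU, the attenuation taken to correspond to alveolar
#' collapse), the HU clamp range, the 3-year observation window, the
#' +/-50-day CT/PFT pairing window and the 6-month minimum follow-up delay.
#'
#' @param hu_threshold Percentile threshold in HU.
#' @param hu_clamp Length-2 HU clamp range (must contain the threshold).
#' @param observation_window_days Outcome window (days).
#' @param pft_pairing_window_days Baseline PFT pairing window (days).
#' @param min_followup_days Minimum follow-up PFT delay (days).
#' @param seed Optional integer seed from which all module substreams are
#'   derived.
#' @return A validated list of class `hushift_config`.
#' @export
analysis_config <- function(hu_threshold = -250, hu_clamp = c(-1024, 200),
                            observation_window_days = 1095,
                            pft_pairing_window_days = 50,
                            min_followup_days = 183, seed = NULL) {
  if (length(hu_clamp) != 2L || hu_clamp[1] >= hu_clamp[2]) {
    abort("`hu_clamp` must be an increasing length-2 numeric",
          class = "hushift_error_spec")
  }
  stopifnot_scalar_num(hu_threshold, "hu_threshold", hu_clamp[1], hu_clamp[2])
  stopifnot_scalar_num(observation_window_days, "observation_window_days", 1)
  stopifnot_scalar_num(pft_pairing_window_days, "pft_pairing_window_days", 1)
  stopifnot_scalar_num(min_followup_days, "min_followup_days", 1)
  structure(
    list(hu_threshold = as.numeric(hu_threshold),
         hu_clamp = as.numeric(hu_clamp),
         observation_window_days = as.numeric(observation_window_days),
         pft_pairing_window_days = as.numeric(pft_pairing_window_days),
         min_followup_days = as.numeric(min_followup_days),
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "hushift_config"
  )
}

#' Write / read an analysis configuration as JSON
#'
#' The round-trip is lossless: `read_config(write_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config A [analysis_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `hushift_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "hushift_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}

#' Write a phantom pair to NIfTI files
#'
#' Volumes are rounded and stored as int16 (the clamp range fits); the mask
#' is stored as int16 labels. Files are `insp.nii.gz`, `exp.nii.gz`,
#' `mask.nii.gz` under `dir`.
#'
#' @param pair A `phantom_pair` from [generate_phantom_pair()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(insp = file.path(dir, "insp.nii.gz"),
             exp = file.path(dir, "exp.nii.gz"),
             mask = file.path(dir, "mask.nii.gz"))
  RNifti::writeNifti(round(pair$insp), paths["insp"], datatype = "int16")
  RNifti::writeNifti(round(pair$exp), paths["exp"], datatype = "int16")
  RNifti::writeNifti(pair$mask, paths["mask"], datatype = "int16")
  invisible(paths)
}

#' Read a paired inspiration/expiration scan with lobe mask(s)
#'
#' Reads NIfTI volumes, checks that each mask shares its volume's grid,
#' and validates mask labels (integer, subset of 0..5).
#'
#' @param insp_path,exp_path Paths to the attenuation volumes.
#' @param mask_path Path to the lobe mask (used for both phases unless
#'   `mask_exp_path` is given).
#' @param mask_exp_path Optional separate expiratory-phase mask.
#' @return A list with arrays `insp`, `exp`, `mask`, `mask_exp`.
#' @export
read_volume_pair <- function(insp_path, exp_path, mask_path,
                             mask_exp_path = NULL) {
  read_arr <- function(p) {
    if (!file.exists(p)) {
      abort(paste0("file not found: ", p), class = "hushift_error_input")
    }
    as.array(RNifti::readNifti(p))
  }
  insp <- read_arr(insp_path); expv <- read_arr(exp_path)
  mask <- read_arr(mask_path)
  mask_exp <- if (!is.null(mask_exp_path)) read_arr(mask_exp_path) else mask
  check_mask <- function(m, vol, what) {
    if (!identical(dim(m), dim(vol))) {
      abort(paste0(what, " mask grid does not match its volume"),
            class = "hushift_error_geometry")
    }
    if (any(m != round(m))) {
      abort(paste0(what, " mask is not integer-labelled"),
            class = "hushift_error_input")
    }
    bad <- setdiff(unique(as.integer(m)), 0:5)
    if (length(bad)) {
      abort(paste0(what, " mask contains unknown labels: ",
                   paste(sort(bad), collapse = ", ")),
            class = "hushift_error_input")
    }
  }
  check_mask(mask, insp, "inspiratory")
  check_mask(mask_exp, expv, "expiratory")
  if (!identical(dim(insp), dim(expv))) {
    abort("inspiratory and expiratory volumes differ in shape",
          class = "hushift_error_geometry")
  }
  list(insp = insp, exp = expv, mask = storage_int(mask),
       mask_exp = storage_int(mask_exp))
}

storage_int <- function(m) {
  array(as.integer(round(m)), dim = dim(m))
}

#' Write / read an analysis cohort as versioned CSV
#'
#' The first line is a schema marker comment; [read_cohort()] refuses files
#' whose schema it does not know, so silently reading an incompatible table
#' is impossible. List-columns (nested PFT series or lobe metrics) are
#' dropped on write.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a tibble.
#' @export
write_cohort <- function(cohort, path) {
  flat <- as_tibble(cohort)
  flat <- flat[, !vapply(flat, is.list, logical(1))]
  writeLines(paste0("# ", COHORT_SCHEMA), path)
  readr::write_csv(flat, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  header <- readLines(path, n = 1L)
  schema <- sub("^#\\s*", "", header)
  if (!identical(schema, COHORT_SCHEMA)) {
    abort(sprintf("unknown cohort schema `%s` (expected `%s`)",
                  schema, COHORT_SCHEMA),
          class = "hushift_error_schema")
  }
  out <- readr::read_csv(path, skip = 1L, show_col_types = FALSE)
  if ("outcome" %in% names(out)) {
    out$outcome <- factor(out$outcome, levels = c("surveillance", "event"))
  }
  out
}

#' Reproducibility manifest for an analysis run
#'
#' Captures everything needed to reproduce a run: package version,
#' configuration snapshot, input-file digests, timestamp, and the
#' per-patient inclusion/exclusion ledger when a built cohort is supplied.
#'
#' @param config A [analysis_config()].
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param cohort Optional cohort from [build_cohort()] whose exclusion
#'   ledger is embedded.
#' @return A list of class `hushift_manifest`.
#' @export
run_manifest <- function(config = analysis_config(), inputs = character(),
                         cohort = NULL) {
  digests <- if (length(inputs)) tools::md5sum(inputs) else
    setNames(character(), character())
  ledger <- NULL
  if (!is.null(cohort)) {
    ledger <- bind_rows(
      tibble(patient_id = cohort$patient_id, status = "included",
             reason = NA_character_),
      mutate(excluded_patients(cohort), status = "excluded")
    )
  }
  structure(
    list(tool = "hushift", version = as.character(packageVersion("hushift")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
         config = unclass(config), input_digests = as.list(digests),
         patients = ledger),
    class = "hushift_manifest"
  )
}
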