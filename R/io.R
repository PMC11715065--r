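#' Read a study dataset from CSV
#'
#' Reads a long-format dataset using NONMEM column conventions: `ID`,
#' `TIME` (min), `EVID` (0 observation, 1 dose), `AMT` (mg), `RATE`
#' (mg/min), `DV`, `DVID` (1 concentration mg/L, 2 R-time min), `MDV`
#' (1 = missing/ignored observation) and `WT` (kg).  Optional columns:
#' `CMT` (1 dabigatran central, 4 reversal compartment; defaults to 1) and
#' `TRUNC` (truncated-at-zero flag, defaults to 0).  Validation errors
#' name the offending row.
#'
#' @param path Path to a CSV file.
#'
#' @return A `study_dataset` data frame (row order preserved).
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(df)
}

#' @describeIn read_dataset Validate (and classify) an in-memory data
#'   frame using the same rules as the reader.
#' @param df A data frame with the columns above.
#' @export
validate_dataset <- function(df) {
  required <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "DVID", "MDV", "WT")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"CMT" %in% names(df)) df$CMT <- 1L
  if (!"TRUNC" %in% names(df)) df$TRUNC <- 0L

  bad_row <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx))
      stop("dataset row ", idx[1], ": ", msg, call. = FALSE)
  }
  bad_row(!is.finite(df$TIME) | df$TIME < 0, "TIME must be non-negative")
  bad_row(!df$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  bad_row(df$EVID == 1L & !is.na(df$DV), "dose row must not carry a DV value")
  bad_row(df$EVID == 1L & (is.na(df$AMT) | df$AMT < 0),
          "dose row needs a non-negative AMT")
  bad_row(df$EVID == 1L & (is.na(df$RATE) | df$RATE <= 0),
          "dose row needs a positive RATE (zero-order input)")
  bad_row(df$EVID == 0L & !df$DVID %in% c(1L, 2L),
          "observation row needs DVID 1 (concentration) or 2 (R-time)")
  bad_row(df$EVID == 0L & df$MDV == 0L & (is.na(df$DV) | df$DV < 0),
          "non-missing observation needs a non-negative DV")
  bad_row(is.na(df$WT) | df$WT <= 0, "WT must be positive")
  wt_per_id <- tapply(df$WT, df$ID, function(w) length(unique(w)))
  if (any(wt_per_id != 1))
    stop("dataset: subject ", names(wt_per_id)[wt_per_id != 1][1],
         " has inconsistent WT values", call. = FALSE)
  class(df) <- c("study_dataset", "data.frame")
  df
}

#' Write a study dataset to CSV
#'
#' Inverse of [read_dataset()]; the round trip is lossless.
#'
#' @param dataset A `study_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

# Compile a dataset into per-subject blocks (regimen + usable observations)
# consumed by the simulation, estimation and VPC machinery.
.compile_dataset <- function(dataset) {
  dataset <- validate_dataset(as.data.frame(dataset))
  ids <- sort(unique(dataset$ID))   # deterministic block order for RNG use
  lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, , drop = FALSE]
    doses <- d[d$EVID == 1L, , drop = FALSE]
    reg <- regimen(drug = ifelse(doses$CMT == 4L, "idarucizumab", "dabigatran"),
                   start = doses$TIME,
                   amount = doses$AMT,
                   duration = doses$AMT / doses$RATE)
    obs <- d[d$EVID == 0L & d$MDV == 0L, c("TIME", "DV", "DVID"), drop = FALSE]
    obs <- obs[order(obs$TIME, obs$DVID), , drop = FALSE]
    list(id = id, weight = d$WT[1], regimen = reg, obs = obs)
  })
}
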