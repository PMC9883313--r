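# Shared validation for identification-record tables.
#
# A record table is a data.frame with one row per identification:
#   individual : character ID of the identified animal
#   event      : character collection-event ID (e.g. encounter x photographer)
#   ordinal    : numeric clock value within the event (frame number, seconds)
#   date       : Date, the sampling period (calendar day)
# plus any number of attribute columns (data_type, effort, unit, ...).

validate_records <- function(records, require_date = TRUE) {
  if (!is.data.frame(records))
    stop("`records` must be a data.frame of identification records",
         call. = FALSE)
  needed <- c("individual", "event", "ordinal")
  if (require_date) needed <- c(needed, "date")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L)
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L)
    stop("records table is empty", call. = FALSE)
  if (!is.numeric(records$ordinal) || any(!is.finite(records$ordinal)))
    stop("`ordinal` must be finite numeric", call. = FALSE)
  records$individual <- as.character(records$individual)
  records$event <- as.character(records$event)
  if (require_date && !inherits(records$date, "Date"))
    records$date <- as.Date(records$date)
  records
}

# Maximum within-event lag present in the data: the largest spread of
# ordinal values inside any single collection event.
max_within_event_lag <- function(records) {
  spread <- tapply(records$ordinal, records$event,
                   function(o) max(o) - min(o))
  max(spread)
}
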