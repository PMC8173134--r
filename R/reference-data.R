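# Published reference values used as pipeline inputs: the per-activity in
# vivo contact excursion table and the in vitro wear-region center, all on
# the representative 43 x 26.5 mm insert.

#' Published in vivo contact excursion table
#'
#' Per-activity mean and SD (across 14 subjects) of the medial contact
#' position on the representative insert: average and range, AP and ML, in
#' mm and normalized percent.  These printed group-level values serve as
#' inputs for the in vivo vs in vitro offset comparison.
#'
#' @return Data frame with one row per activity (`stance`, `lunge`,
#'   `sit_to_stand`), columns `<dir>_<avg|range>[_pct]_<mean|sd>`.
#' @export
invivo_contact_table <- function() {
  data.frame(
    activity = c("stance", "lunge", "sit_to_stand"),
    ap_avg_mean = c(5.2, 1.0, 2.1),  ap_avg_sd = c(2.7, 2.4, 3.3),
    ap_avg_pct_mean = c(12.0, 2.4, 4.9), ap_avg_pct_sd = c(6.2, 5.5, 7.6),
    ap_range_mean = c(6.0, 7.9, 8.6), ap_range_sd = c(1.6, 2.7, 2.6),
    ap_range_pct_mean = c(13.9, 18.5, 19.9),
    ap_range_pct_sd = c(3.7, 6.4, 6.0),
    ml_avg_mean = c(1.8, 0.9, 1.4),  ml_avg_sd = c(1.6, 1.5, 1.4),
    ml_avg_pct_mean = c(6.8, 3.3, 5.5), ml_avg_pct_sd = c(6.2, 5.6, 5.5),
    ml_range_mean = c(1.9, 2.4, 2.2), ml_range_sd = c(0.6, 1.3, 1.2),
    ml_range_pct_mean = c(7.5, 9.2, 8.3), ml_range_pct_sd = c(2.3, 5.2, 4.5))
}

#' Published in vivo vs in vitro contact offsets
#'
#' Group-level offsets (in vivo average contact minus in vitro wear-region
#' center) per activity and direction, recomputed by
#' [offset_vs_reference()] from [invivo_contact_table()] and
#' [wear_reference_center()].
#'
#' @return Data frame: `activity`, `ap_offset`, `ml_offset` (mm).
#' @export
published_contact_offsets <- function() {
  tab <- invivo_contact_table()
  ref <- wear_reference_center()
  data.frame(activity = tab$activity,
             ap_offset = tab$ap_avg_mean - ref$ap_mm,
             ml_offset = tab$ml_avg_mean - ref$ml_mm)
}
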