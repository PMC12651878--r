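#' Rule-based AJCC stage for pancreatic neuroendocrine tumors
#'
#' The committee rule mapping TNM levels to stages I-IV: any distant
#' metastasis (M1) is stage IV; otherwise nodal involvement (N1) or a T4
#' tumor is stage III; otherwise T2 or T3 is stage II and T1N0M0 is
#' stage I. Over the 16 TNM combinations this partitions 1/2/5/8 cells
#' across stages I-IV.
#'
#' @param t,n,m Character vectors of T (\code{"T1"}-\code{"T4"}), N
#'   (\code{"N0"}/\code{"N1"}) and M (\code{"M0"}/\code{"M1"}) levels;
#'   recycled to a common length.
#' @return Ordered factor of stages with levels \code{I < II < III < IV}.
#' @examples
#' assign_ajcc_stage("T1", "N0", "M0")  # stage I
#' assign_ajcc_stage("T3", "N1", "M0")  # stage III
#' @export
assign_ajcc_stage <- function(t, n, m) {
  len <- max(length(t), length(n), length(m))
  t <- rep_len(as.character(t), len)
  n <- rep_len(as.character(n), len)
  m <- rep_len(as.character(m), len)
  if (!all(t %in% paste0("T", 1:4))) stop("invalid T level")
  if (!all(n %in% c("N0", "N1"))) stop("invalid N level")
  if (!all(m %in% c("M0", "M1"))) stop("invalid M level")
  stage <- ifelse(m == "M1", "IV",
           ifelse(n == "N1" | t == "T4", "III",
           ifelse(t %in% c("T2", "T3"), "II", "I")))
  factor(stage, levels = c("I", "II", "III", "IV"), ordered = TRUE)
}
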