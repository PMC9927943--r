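#' CKD-EPI 2009 creatinine eGFR
#'
#' eGFR = 141 * min(Scr/k, 1)^alpha * max(Scr/k, 1)^-1.209 * 0.993^age *
#' 1.018[female], with k = 0.7 (F) / 0.9 (M) and alpha = -0.329 (F) /
#' -0.411 (M). No race term.
#'
#' @param creatinine serum creatinine in mg/dL, > 0.
#' @param age years, > 0.
#' @param sex "male"/"female" (or "M"/"F", case-insensitive).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckd_epi_egfr <- function(creatinine, age, sex) {
  if (any(creatinine <= 0) || any(age <= 0)) stop("non-positive inputs")
  sx <- tolower(substr(as.character(sex), 1, 1))
  if (!all(sx %in% c("m", "f"))) stop("sex must be male/female")
  female <- sx == "f"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(creatinine / kappa, 1)^alpha *
    pmax(creatinine / kappa, 1)^-1.209 *
    0.993^age * ifelse(female, 1.018, 1)
}

#' Albuminuria category from UACR or AER
#'
#' A1 below 30, A2 from 30 to 300 inclusive, A3 above 300 — the same numeric
#' cutoffs for UACR (mg/g) and AER (mg/24 h). The lower boundary 30 is
#' assigned upward (A2); 300 stays in A2.
#'
#' @param uacr urinary albumin-to-creatinine ratio, mg/g (or NULL).
#' @param aer albumin excretion rate, mg/24 h (used when `uacr` is NULL).
#' @return character vector "A1"/"A2"/"A3".
#' @export
albuminuria_stage <- function(uacr = NULL, aer = NULL) {
  v <- if (!is.null(uacr)) uacr else aer
  if (is.null(v)) stop("both measures missing")
  if (any(v < 0)) stop("albuminuria measure must be >= 0")
  ifelse(v < 30, "A1", ifelse(v <= 300, "A2", "A3"))
}

#' Map albuminuria category to cohort stage labels
#'
#' A1 -> Normo, A2 -> Micro, A3 -> Macro.
#' @param acat character vector "A1"/"A2"/"A3".
#' @return character vector of stage labels.
#' @export
albuminuria_label <- function(acat) {
  c(A1 = "Normo", A2 = "Micro", A3 = "Macro")[acat]
}

# KDIGO G x A risk matrix (rows G1..G5, columns A1..A3)
.kdigo_matrix <- matrix(
  c("low",       "moderate",  "high",
    "low",       "moderate",  "high",
    "moderate",  "high",      "very_high",
    "high",      "very_high", "very_high",
    "very_high", "very_high", "very_high",
    "very_high", "very_high", "very_high"),
  nrow = 6, byrow = TRUE,
  dimnames = list(c("G1", "G2", "G3a", "G3b", "G4", "G5"),
                  c("A1", "A2", "A3")))

#' GFR category from eGFR
#'
#' Bands: G1 >= 90, G2 60-89, G3a 45-59, G3b 30-44, G4 15-29, G5 < 15.
#' @param egfr eGFR in mL/min/1.73 m^2.
#' @return character vector of G categories.
#' @export
gfr_category <- function(egfr) {
  if (any(egfr <= 0)) stop("eGFR must be positive")
  cut(egfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf), right = FALSE,
      labels = c("G5", "G4", "G3b", "G3a", "G2", "G1")) |> as.character()
}

#' KDIGO risk category
#'
#' Combines the GFR category (from eGFR) and albuminuria category through the
#' standard KDIGO G x A risk matrix into low/moderate/high/very_high. An ESRD
#' flag (dialysis or transplant) forces G5 and very high risk regardless of
#' eGFR.
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (may be NA where `esrd` is TRUE).
#' @param albuminuria character "A1"/"A2"/"A3".
#' @param esrd logical flag (recycled).
#' @return data.frame with `gfr_category`, `albuminuria_category`, `risk`
#'   (ordered factor low < moderate < high < very_high).
#' @export
kdigo_risk <- function(egfr, albuminuria, esrd = FALSE) {
  egfr <- as.numeric(egfr)
  n <- max(length(egfr), length(albuminuria))
  esrd <- rep_len(esrd, n)
  if (!all(albuminuria %in% colnames(.kdigo_matrix)))
    stop("invalid albuminuria category")
  g <- rep(NA_character_, n)
  need <- !esrd
  if (any(need & (is.na(egfr) | egfr <= 0)))
    stop("eGFR must be positive unless the ESRD flag is set")
  g[need] <- gfr_category(egfr[need])
  g[esrd] <- "G5"
  risk <- .kdigo_matrix[cbind(g, rep_len(albuminuria, n))]
  data.frame(gfr_category = g, albuminuria_category = rep_len(albuminuria, n),
             risk = factor(risk, levels = c("low", "moderate", "high",
                                            "very_high"), ordered = TRUE))
}
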