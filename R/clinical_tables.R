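# Bundled example contingency tables: clinical features x integrative
# subtype for a published TCGA endometrial-carcinoma cohort (421
# samples, three integrative subtypes iC1/iC2/iC3). Used as worked
# examples for chi2_contingency() and by the acceptance report.

#' Clinical-feature contingency tables of the reference EC cohort
#'
#' Feature-by-subtype count tables (columns iC1, iC2, iC3) for a
#' 421-sample endometrial-carcinoma cohort: vital status, FIGO stage,
#' histologic grade, recurrence type, age decade, and body-mass-index
#' quartile. The grade table's G4 row has no iC3 members (count 0).
#' The `new_event_type` table includes an "Un" (unknown) row that the
#' published analysis excluded before testing; pass
#' `drop_levels = "Un"` to [chi2_contingency()] to reproduce it.
#'
#' @return named list of integer matrices: `event`, `stage`, `grade`,
#'   `new_event_type`, `age`, `bmi`.
#' @export
ec_clinical_tables <- function() {
  sub <- c("iC1", "iC2", "iC3")
  mk <- function(v, rn) matrix(v, ncol = 3, byrow = TRUE,
                               dimnames = list(rn, sub))
  list(
    event = mk(c(84, 92, 175,
                 10, 35, 23,
                 1, 1, 0),
               c("Alive", "Dead", "NA")),
    stage = mk(c(65, 49, 141,
                 7, 16, 19,
                 18, 49, 33,
                 5, 14, 5),
               c("I", "II", "III", "IV")),
    grade = mk(c(7, 2, 51,
                 10, 9, 68,
                 75, 109, 79,
                 3, 8, 0),
               c("G1", "G2", "G3", "G4")),
    new_event_type = mk(c(3, 3, 6,
                          2, 15, 8,
                          4, 1, 0,
                          83, 99, 179,
                          3, 10, 5),
                        c("Distant Metastasis", "Locoregional Recurrence",
                          "New Primary Tumor", "Primary", "Un")),
    age = mk(c(16, 0, 21,
               21, 17, 62,
               33, 56, 64,
               18, 37, 37,
               7, 18, 14),
             c("31~50", "50~60", "60~70", "70~80", "80~90")),
    bmi = mk(c(37, 45, 36,
               22, 34, 50,
               13, 29, 52,
               23, 20, 60),
             c("0~26.22", "26.22~32.24", "32.24~38.69", "38.69~214")))
}
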