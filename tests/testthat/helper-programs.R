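# Hand-traced drug-program fixtures exercising every classification
# rule: phase advancement, the 2-year inactivity rule, manufacturer
# withdrawal, missed primary endpoints, ongoing censoring, phase I/II
# hybrids, mid-stream entry, and biomarker status.  Expected outcomes
# were derived by hand from the rules, not from package output.

REF_DATE <- as.Date("2017-01-02")

mk_trial <- function(drug, ind, phase, start, comp = NA, bm = 0L,
                     bm_ids = "", appr = 0L, appr_date = NA, wd = 0L,
                     fe = 0L) {
  data.frame(
    drug_id = drug, indication = ind, phase = phase,
    start_date = as.Date(start), completion_date = as.Date(comp),
    uses_biomarker_selection = bm, biomarker_ids = bm_ids,
    fda_approved = appr, approval_date = as.Date(appr_date),
    withdrawn = wd, failed_endpoint = fe, stringsAsFactors = FALSE)
}

fixture_registry <- function() {
  data.frame(
    biomarker_id = c("ALK", "KRAS", "HER2"),
    indication = c("nsclc", "colorectal", "breast"),
    fda_approval_date = as.Date(c("2009-08-26", "2009-07-01",
                                  "1998-09-25")),
    stringsAsFactors = FALSE)
}

fixture_trials <- function() {
  rbind(
    # P01: full path to approval
    mk_trial("P01", "breast", "I",   "2005-01-01", "2006-01-01"),
    mk_trial("P01", "breast", "II",  "2006-06-01", "2008-06-01"),
    mk_trial("P01", "breast", "III", "2009-01-01", "2011-01-01",
             appr = 1L, appr_date = "2012-03-01"),
    # P02: phase I failure by >2y inactivity
    mk_trial("P02", "colorectal", "I", "2010-01-01", "2013-01-01"),
    # P03: phase I ongoing (completed inside the 2-year window)
    mk_trial("P03", "melanoma", "I", "2015-06-01", "2016-06-01"),
    # P04: I success, II ongoing (no completion date)
    mk_trial("P04", "nsclc", "I",  "2010-01-01", "2011-01-01"),
    mk_trial("P04", "nsclc", "II", "2011-06-01"),
    # P05: manufacturer withdrawal at phase II
    mk_trial("P05", "breast", "I",  "2008-01-01", "2009-01-01"),
    mk_trial("P05", "breast", "II", "2009-06-01", "2010-06-01", wd = 1L),
    # P06: I/II hybrid counts as phase I; II ongoing
    mk_trial("P06", "nsclc", "I_II", "2014-01-01", "2015-01-01"),
    mk_trial("P06", "nsclc", "II",   "2015-03-01", "2016-09-01"),
    # P07: phase III failure by inactivity, I and II successes
    mk_trial("P07", "colorectal", "I",   "2006-01-01", "2007-01-01"),
    mk_trial("P07", "colorectal", "II",  "2007-06-01", "2009-06-01"),
    mk_trial("P07", "colorectal", "III", "2010-01-01", "2013-06-01"),
    # P08: primary endpoints missed at phase II
    mk_trial("P08", "melanoma", "I",  "2012-01-01", "2013-01-01"),
    mk_trial("P08", "melanoma", "II", "2013-03-01", "2015-09-01",
             fe = 1L),
    # P09: enters development mid-stream at phase II, ongoing
    mk_trial("P09", "breast", "II", "2016-01-01"),
    # P10: approved, biomarker used >2y after its approval (validated)
    mk_trial("P10", "nsclc", "I",   "2013-01-01", "2013-10-01",
             bm = 1L, bm_ids = "ALK"),
    mk_trial("P10", "nsclc", "II",  "2014-01-01", "2015-01-01",
             bm = 1L, bm_ids = "ALK"),
    mk_trial("P10", "nsclc", "III", "2015-03-01", "2016-06-01",
             bm = 1L, bm_ids = "ALK", appr = 1L,
             appr_date = "2016-12-01"),
    # P11: phase II completed 6 months before the reference: ongoing
    mk_trial("P11", "nsclc", "I",  "2012-01-01", "2013-06-01"),
    mk_trial("P11", "nsclc", "II", "2014-01-01", "2016-07-01"),
    # P12: exploratory biomarker (never approved in indication)
    mk_trial("P12", "breast", "I",  "2014-01-01", "2015-01-01",
             bm = 1L, bm_ids = "BRCA1"),
    mk_trial("P12", "breast", "II", "2015-06-01")
  )
}

# expected (phase -> status) per program at REF_DATE, hand-derived
fixture_expected_outcomes <- function() {
  list(
    P01 = c(I = "success", II = "success", III = "success"),
    P02 = c(I = "failure"),
    P03 = c(I = "ongoing"),
    P04 = c(I = "success", II = "ongoing"),
    P05 = c(I = "success", II = "failure"),
    P06 = c(I = "success", II = "ongoing"),
    P07 = c(I = "success", II = "success", III = "failure"),
    P08 = c(I = "success", II = "failure"),
    P09 = c(II = "ongoing"),
    P10 = c(I = "success", II = "success", III = "success"),
    P11 = c(I = "success", II = "ongoing"),
    P12 = c(I = "success", II = "ongoing")
  )
}

# expected terminal row of each state history: exact state, or the
# censoring set for ongoing programs
fixture_expected_terminal <- function() {
  list(
    P01 = list(state = 4L), P02 = list(state = 5L),
    P03 = list(censor = "1,2,3,4"), P04 = list(censor = "2,3,4"),
    P05 = list(state = 5L), P06 = list(censor = "2,3,4"),
    P07 = list(state = 5L), P08 = list(state = 5L),
    P09 = list(censor = "2,3,4"), P10 = list(state = 4L),
    P11 = list(censor = "2,3,4"), P12 = list(censor = "2,3,4")
  )
}
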