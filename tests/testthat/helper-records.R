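# builders for small record fixtures, constructed in code

blank_pd <- function() {
  stats::setNames(as.list(numeric(52)), pd_column_names())
}

make_record <- function(patient_id = "P1", eye = "R",
                        test_date = as.Date("2016-06-01"),
                        age = 60, se_diopters = 0, md_db = 0,
                        psd_abnormal = FALSE, ght = "WNL",
                        fixation_loss_rate = 0.1, fp_rate = 0.05,
                        fn_rate = 0.05, nbsl_h = 14, nbsl_v = -2,
                        pd = NULL) {
  rec <- data.frame(patient_id = patient_id, eye = eye,
                    test_date = test_date, age = age,
                    se_diopters = se_diopters, md_db = md_db,
                    psd_abnormal = psd_abnormal, ght = ght,
                    fixation_loss_rate = fixation_loss_rate,
                    fp_rate = fp_rate, fn_rate = fn_rate,
                    nbsl_h = nbsl_h, nbsl_v = nbsl_v,
                    stringsAsFactors = FALSE)
  pdv <- blank_pd()
  if (!is.null(pd)) pdv[names(pd)] <- pd
  cbind(rec, as.data.frame(pdv, check.names = FALSE))
}

make_records <- function(n, ...) {
  args <- list(...)
  do.call(rbind, lapply(seq_len(n), function(i) {
    one <- lapply(args, function(a) if (length(a) >= n) a[[i]] else a)
    one$patient_id <- if (!is.null(args$patient_id)) one$patient_id
                      else sprintf("P%03d", i)
    do.call(make_record, one)
  }))
}

# frequency table built directly from cell counts given as a data frame
make_freq_table <- function(h, v, count) {
  cells <- data.frame(h_deg = h, v_deg = v, count = count)
  path <- tempfile(fileext = ".csv")
  cells$bracketed <- as.integer(cells$count < 5)
  write.csv(cells, path, row.names = FALSE)
  on.exit(unlink(path))
  read_frequency_table(path)
}
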