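test_that("spike_train validates and sorts its input", {
  tr <- spike_train("u1", 3L, c(2, 1, 3))
  expect_equal(tr$spike_times, c(1, 2, 3))
  expect_error(spike_train("u1", 0L, 1), "channel_id")
  expect_error(spike_train("u1", 9L, 1), "channel_id")
  expect_error(spike_train("u1", 1L, c(1, NA)), "NA")
  expect_error(spike_train("u1", 1L, -1), "out of range")
})

test_that("epoch enforces duration bounds and unique unit ids", {
  t1 <- spike_train("u1", 1L, c(0, 10))
  t2 <- spike_train("u2", 2L, c(5, 299))
  ep <- epoch("e1", "P1", list(t1, t2))
  expect_equal(length(ep$trains), 2L)
  expect_error(epoch("e1", "P1", list(t1, t1)), "duplicate unit_id")
  expect_error(epoch("e1", "P1", list(spike_train("u3", 1L, 400))),
               "out of range")
  expect_error(epoch("e1", "P1", list(), duration_s = 0), "duration_s")
})

test_that("session round trip through csv and json is the identity", {
  t1 <- spike_train("u1", 1L, c(0.25, 10.123456))
  t2 <- spike_train("u2", 2L, c(5, 290))
  cv <- anesthesia_record(sevoflurane_pct = 2.1, fentanyl_use = "induction",
                          midazolam_at_induction = TRUE)
  s <- spike_session(list(
    epoch("e1", "P1", list(t1, t2), covariates = cv),
    epoch("e2", "P1", list(spike_train("u3", 4L, 1.5)), duration_s = 120),
    epoch("e1", "P2", list())))
  for (fmt in c("csv", "json")) {
    path <- file.path(tempdir(), paste0("sess.", fmt))
    write_session(s, path, fmt)
    s2 <- load_session(path, fmt)
    expect_equal(unit_count_table(s2), unit_count_table(s))
    expect_equal(s2$epochs[[1]]$trains$u1$spike_times, t1$spike_times)
    expect_equal(s2$epochs[[1]]$covariates$sevoflurane_pct, 2.1)
    expect_equal(s2$epochs[[1]]$covariates$fentanyl_use, "induction")
    expect_equal(s2$epochs[[2]]$duration_s, 120)
  }
})

test_that("write_session output is byte-stable", {
  s <- spike_session(list(epoch("e1", "P1",
                                list(spike_train("u1", 1L, c(1, 2, 3))))))
  p1 <- file.path(tempdir(), "a.csv"); p2 <- file.path(tempdir(), "b.csv")
  write_session(s, p1); write_session(s, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a session with no epochs writes and loads as a valid empty file", {
  s <- spike_session(list())
  path <- file.path(tempdir(), "empty.csv")
  write_session(s, path)
  s2 <- load_session(path)
  expect_equal(length(s2$epochs), 0L)
  expect_equal(nrow(unit_count_table(s2)), 0L)
})

test_that("load_session rejects out-of-range spike times", {
  path <- file.path(tempdir(), "bad.csv")
  writeLines(c("patient_id,epoch_id,unit_id,channel_id,spike_time_s",
               "P1,e1,u1,1,-1.000000"), path)
  jsonlite::write_json(
    list(list(patient_id = "P1", epoch_id = "e1", duration_s = 300,
              covariates = NULL,
              units = list(list(unit_id = "u1", channel_id = 1)))),
    file.path(tempdir(), "bad_meta.json"), auto_unbox = TRUE)
  expect_error(load_session(path), "out of range")
})

test_that("unit_count_table conserves the number of trains", {
  gen <- generate_population(population_config(
    layout = data.frame(patient_id = c("P1", "P1", "P2"),
                        epoch_id = c("e1", "e2", "e1"),
                        n_units = c(3L, 2L, 4L)),
    epoch_duration_s = 30, seed = 5))
  tab <- unit_count_table(gen$session)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$n_units), 9L)
  expect_equal(tab$n_units,
               vapply(gen$session$epochs, function(e) length(e$trains), 0L))
})

test_that("the bundled epoch layout matches the emulated study shape", {
  lay <- default_epoch_layout()
  expect_equal(nrow(lay), 37L)
  expect_equal(length(unique(lay$patient_id)), 14L)
  expect_equal(sum(lay$n_units), 222L)
})
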