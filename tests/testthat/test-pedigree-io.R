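test_that("pedigree construction validates ids and augments missing parents", {
  ped <- pedigree(data.frame(id = c("A", "B", "C"),
                             sire = c("0", "", "A"),
                             dam = c(NA, "NA", "B")))
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_true(all(is.na(ped$sire[ped$id %in% c("A", "B")])))

  # parents appearing only in parent columns are materialized as founders
  expect_message(aug <- pedigree(data.frame(id = "C", sire = "A", dam = "B")),
                 "auto-created")
  expect_equal(nrow(aug), 3)
  expect_setequal(aug$id, c("A", "B", "C"))
  expect_equal(attr(aug, "n_autocreated"), 2L)
  expect_equal(aug$sex[aug$id == "A"], "M")  # inferred from sire role

  expect_error(pedigree(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
               "duplicate")
  expect_error(pedigree(data.frame(id = "A", sire = "A", dam = NA)),
               "own parent")
})

test_that("read/write round-trips both dialects and preserves unknowns", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,sex,birth_year,studbook,in_reference,extra",
               "A,0,0,M,1999,sp,0,x",
               "B,,,F,2000,,0,y",
               "C,A,B,F,2004,sp,1,z"), csv)
  ped <- read_pedigree(csv, dialect = "csv")
  expect_equal(nrow(ped), 3)
  expect_true(ped$in_reference[ped$id == "C"])
  expect_true(is.na(ped$studbook[ped$id == "B"]))

  out <- tempfile(fileext = ".csv")
  write_pedigree(ped, out)
  again <- read_pedigree(out)
  expect_identical(as.data.frame(ped), as.data.frame(again))

  tc <- tempfile(fileext = ".txt")
  writeLines(c("A 0 0", "B 0 0", "C A B"), tc)
  ped3 <- read_pedigree(tc, dialect = "three_column")
  expect_equal(sum(is.na(ped3$sire) & is.na(ped3$dam)), 2)
  expect_error(read_pedigree(tempfile(), "csv"), "not found")
})

test_that("topological order is stable, idempotent and cycle-aware", {
  # already parent-first input comes back unchanged (stability)
  df <- data.frame(id = c("A", "C", "B"),
                   sire = c(NA, "A", NA), dam = c(NA, NA, NA))
  ped <- pedigree(df)
  expect_equal(ped$id, c("A", "C", "B"))
  expect_equal(topological_order(ped)$id, ped$id)

  # offspring listed before its parents gets moved after them
  df2 <- data.frame(id = c("C", "A", "B"), sire = c("A", NA, NA),
                    dam = c("B", NA, NA))
  ped2 <- pedigree(df2)
  expect_true(which(ped2$id == "C") > max(which(ped2$id %in% c("A", "B"))))

  chain <- make_toy("chain15")
  par <- studbook:::ped_parents(chain)
  expect_true(all(par$sire < seq_len(nrow(chain)) | par$sire == 0))
  expect_true(all(par$dam < seq_len(nrow(chain)) | par$dam == 0))

  cyc <- data.frame(id = c("A", "B"), sire = c("B", "A"), dam = c(NA, NA))
  expect_error(pedigree(cyc), "cycle")
})

test_that("validate_pedigree reports role conflicts and chronology warnings", {
  ped <- pedigree(data.frame(
    id = c("X", "P", "C", "D"),
    sire = c(NA, NA, "X", NA),
    dam = c(NA, NA, "P", "X"),
    sex = c("U", "F", "F", "M"),
    birth_year = c(2005L, 2000L, 2003L, 2010L)))
  rep <- validate_pedigree(ped)
  expect_true(any(rep$code == "role_conflict" & rep$severity == "error"))
  # C (2003) born before sire X (2005): warning, not error
  expect_true(any(rep$code == "chronology" & rep$severity == "warning"))

  clean <- validate_pedigree(make_toy("full_sib_mating"))
  expect_false(any(clean$severity == "error"))

  sexed <- pedigree(data.frame(id = c("F1", "D1", "K"), sire = c(NA, NA, "F1"),
                               dam = c(NA, NA, "D1"),
                               sex = c("F", "F", "U")))
  expect_true(any(validate_pedigree(sexed)$code == "sex_conflict"))
})

test_that("auto-created founder count equals referenced minus listed ids", {
  for (seed in 1:5) {
    set.seed(seed)
    ids <- sprintf("A%02d", 1:20)
    sire <- sample(c(sprintf("S%02d", 1:6), NA), 20, replace = TRUE)
    dam <- sample(c(sprintf("D%02d", 1:6), NA), 20, replace = TRUE)
    suppressMessages(ped <- pedigree(data.frame(id = ids, sire = sire, dam = dam)))
    referenced <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
    expect_equal(attr(ped, "n_autocreated"), length(setdiff(referenced, ids)))
    expect_equal(nrow(ped), 20 + length(setdiff(referenced, ids)))
  }
})

test_that("write_report emits csv and lossless json", {
  tab <- data.frame(group = c("a", "b"), value = c(pi, exp(1)))
  f <- tempfile(fileext = ".csv")
  write_report(tab, f, format = "csv")
  back <- read.csv(f)
  expect_equal(back$value, tab$value, tolerance = 1e-12)

  j <- tempfile(fileext = ".json")
  write_report(list(stats = tab, meta = list(seed = 3L)), j, format = "json")
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(parsed$stats$value, tab$value, tolerance = 1e-12)
  expect_equal(parsed$meta$seed, 3L)

  empty <- data.frame(group = character(0), value = numeric(0))
  f2 <- tempfile(fileext = ".csv")
  write_report(empty, f2)
  expect_equal(nrow(read.csv(f2)), 0)
})
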