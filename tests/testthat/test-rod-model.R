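test_that("FASTA records are parsed, ordered and normalized", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rodA some description", "MKELQDRLAK",
               ">rodB", "acdefghikl", "mn"), fa)
  recs <- read_rod_fasta(fa)
  expect_tibble(recs, c("id", "sequence", "rod_start", "rod_end"))
  expect_equal(recs$id, c("rodA", "rodB"))
  expect_equal(nchar(recs$sequence), c(10L, 12L))
  expect_equal(recs$sequence[2], "ACDEFGHIKLMN") # lowercase accepted
  expect_equal(recs$rod_start, c(1L, 1L))
  expect_equal(recs$rod_end, c(10L, 12L))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_rod_fasta(empty), "empty")
  expect_error(read_rod_fasta(file.path(tempdir(), "nope.fasta")),
               "not found")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "MKEL1QD"), bad)
  expect_error(read_rod_fasta(bad))
})

test_that("rod_record validates boundaries and skip positions", {
  expect_error(rod_record("x", "MKEL", rod_start = 3, rod_end = 2), "rod_start")
  expect_error(rod_record("x", "MKEL", rod_end = 9), "rod_start")
  expect_error(rod_record("x", "MKELMKEL", rod_start = 3, rod_end = 6,
                          skip_positions = 7), "skip_positions")
  expect_error(rod_record("x", "MKXL"), "non-standard")
  r <- rod_record("x", "mkelmkel", rod_start = 2, rod_end = 7,
                  skip_positions = c(4, 4))
  expect_equal(r$sequence, "MKELMKEL")
  expect_equal(r$skip_positions[[1]], 4L)
})

test_that("fallback register cycles a..g and skips interrupt without advancing", {
  r7 <- rod_record("r7", "AAAAAAA")
  expect_equal(assign_register(r7, phase = "a")$label, letters[1:7])

  r8 <- rod_record("r8", "AAAAAAAA", skip_positions = 4)
  lab <- assign_register(r8, phase = "a")$label
  expect_equal(lab, c("a", "b", "c", "skip", "d", "e", "f", "g"))

  # arbitrary phase on a rod sub-interval
  r <- rod_record("r", "MMAAAAAAAA", rod_start = 3, rod_end = 10)
  expect_equal(assign_register(r, phase = "e")$label[1:4],
               c("e", "f", "g", "a"))
})

test_that("file-mode register is passed through verbatim and validated", {
  r <- rod_record("r", "AAAAAAAAAA")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  lab <- c("c", "d", "e", "f", "g", "skip", "a", "b", "c", "none")
  write.table(data.frame(residue_index = 1:10, label = lab), tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- assign_register(r, "file", tsv)
  expect_equal(reg$label, lab)

  short <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(residue_index = 1:9, label = lab[1:9]), short,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(assign_register(r, "file", short), "9 rows")

  badlab <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(residue_index = 1:10,
                         label = c(lab[1:9], "q")), badlab,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(assign_register(r, "file", badlab), "invalid register label")
})

test_that("charge assignment: R/K +2e, D/E -2e, a/d cancelled, skips kept", {
  # register phase a: positions 1=a, 2=b, ..., 4=d
  r <- rod_record("r", "KKEGDRE")
  reg <- assign_register(r, phase = "a")
  ch <- build_charge_chain(r, reg)
  # K at a -> 0; K at b -> +2; E at c -> -2; G -> 0; D at e... wait d=pos4
  expect_equal(ch$charge, c(0, 2, -2, 0, -2, 2, -2))
  expect_equal(ch$position_nm[1], 0)
  expect_equal(diff(ch$position_nm), rep(0.1456, 6))

  # lysine at register e keeps +2e; glutamate at a is cancelled
  r2 <- rod_record("r2", "EAAAKAA")
  ch2 <- build_charge_chain(r2, assign_register(r2, phase = "a"))
  expect_equal(ch2$charge[1], 0)  # E at a
  expect_equal(ch2$charge[5], 2)  # K at e

  # a charged skip residue survives cancellation
  r3 <- rod_record("r3", "AAAKAAAA", skip_positions = 4)
  ch3 <- build_charge_chain(r3, assign_register(r3, phase = "a"))
  expect_equal(ch3$register[4], "skip")
  expect_equal(ch3$charge[4], 2)
  expect_equal(nrow(ch3), 8) # skip residues are charge sites

  # site index 10 sits at 1.456 nm
  r4 <- rod_record("r4", strrep("A", 12))
  ch4 <- build_charge_chain(r4, assign_register(r4))
  expect_equal(ch4$position_nm[ch4$site == 10], 1.456)
})

test_that("charge conservation and reversal symmetry hold on random rods", {
  for (seed in 1:5) {
    set.seed(seed)
    res <- sample(c("A", "K", "R", "E", "D", "L", "G", "S"), 60,
                  replace = TRUE)
    r <- rod_record("rnd", paste(res, collapse = ""))
    reg <- assign_register(r, phase = "c")
    ch <- build_charge_chain(r, reg)
    per_site <- ifelse(reg$label %in% c("a", "d"), 0,
                       dplyr::case_when(res %in% c("K", "R") ~ 2,
                                        res %in% c("D", "E") ~ -2,
                                        TRUE ~ 0))
    expect_equal(sum(ch$charge), sum(per_site))
    expect_equal(ch$charge, per_site)

    # reversing sequence and register reverses the charge array exactly
    rrev <- rod_record("rev", paste(rev(res), collapse = ""))
    regrev <- reg
    regrev$residue <- rev(reg$residue)
    regrev$label <- rev(reg$label)
    chrev <- build_charge_chain(rrev, regrev)
    expect_equal(chrev$charge, rev(ch$charge))
  }
})

test_that("sliding-window profile gives exact sums at window midpoints", {
  z <- as_chain(rep(0, 120))
  p0 <- charge_profile(z, 98)
  expect_true(all(p0$net_charge_e == 0))
  expect_equal(nrow(p0), 120 - 98 + 1)

  full <- as_chain(rep(2, 98))
  p1 <- charge_profile(full, 98)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$net_charge_e, 196)
  expect_equal(p1$center_nm, (0 + 97 * 0.1456) / 2)

  expect_error(charge_profile(full, 99), "window")

  ch <- random_chain(250, 11)
  p <- charge_profile(ch, 30)
  brute <- vapply(seq_len(250 - 30 + 1), function(i)
    sum(ch$charge[i:(i + 29)]), numeric(1))
  expect_equal(p$net_charge_e, brute)
})

test_that("charge chains round-trip through TSV export", {
  ch <- synthetic_rod(n_sites = 300, tip_sites = 10)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_charge_chain(ch, tsv)
  back <- read_charge_chain(tsv)
  expect_equal(back$charge, ch$charge)
  expect_equal(back$position_nm, ch$position_nm)
  expect_equal(attr(back, "label"), attr(ch, "label"))
})
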