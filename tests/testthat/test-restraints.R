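test_that("PRE restraints apply the ratio cutoff, padding and bound conventions", {
  p <- sbmf_parameters()
  tag_map <- data.frame(tag_site = "B5C", chain = "B", resno = 5)
  g20 <- gamma2_from_distance(20, p)
  meas <- data.frame(tag_site = "B5C", chain = "A", resnum = 1:3, probe = "N",
                     ratio = c(0.9, 0.4, 0.6),
                     gamma2 = c(1, g20, 30), status = "quantified")
  rs <- build_pre_restraints(meas, p, tag_map)
  expect_equal(rs$status, c("filtered_ratio", "retained", "retained"))
  expect_equal(rs$upper[2], 26.0, tolerance = 1e-9)   # 20 A + 6 A padding
  expect_equal(rs$lower, rep(0, 3))
  expect_equal(rs$atom_b, rep("CB", 3))
  # all quantified and below the cutoff: conservation of count
  meas2 <- data.frame(tag_site = "B5C", chain = "A", resnum = 1:14, probe = "N",
                      ratio = 0.5, gamma2 = 20, status = "quantified")
  expect_equal(sum(build_pre_restraints(meas2, p, tag_map)$status == "retained"),
               14)
  # bleached rows are excluded but counted
  meas3 <- rbind(meas, data.frame(tag_site = "B5C", chain = "A", resnum = 4,
                                  probe = "N", ratio = NA, gamma2 = NA,
                                  status = "bleached"))
  rs3 <- build_pre_restraints(meas3, p, tag_map)
  expect_equal(nrow(rs3), 3)
  expect_equal(attr(rs3, "n_bleached"), 1)
  expect_error(build_pre_restraints(transform(meas, tag_site = "Z9C"), p,
                                    tag_map), "Z9C")
})

test_that("encounter-satisfiable filtering retains 8 of 14 on the mirrored fixture", {
  fx <- encounter_fixture()
  out <- filter_encounter_satisfiable(fx$restraints, list(fx$model))
  expect_equal(attr(out, "n_eliminated"), 6)
  expect_equal(attr(out, "n_retained"), 8)
  expect_equal(sum(out$status == "eliminated_encounter") +
                 sum(out$status == "retained"), 14)
  # order-independent: statuses follow the geometry
  expect_true(all(out$status[1:6] == "eliminated_encounter"))
  expect_true(all(out$status[7:14] == "retained"))
})

test_that("the ANY-member rule and bound monotonicity govern elimination", {
  fx <- encounter_fixture()
  far <- fx$model
  far$atoms$x <- far$atoms$x + c(rep(100, 14), 0)  # push probes far away
  # all bounds below all distances: nothing eliminated
  out <- filter_encounter_satisfiable(fx$restraints, list(far))
  expect_equal(attr(out, "n_eliminated"), 0)
  # satisfied in exactly one of several members: still eliminated
  out2 <- filter_encounter_satisfiable(fx$restraints,
                                       list(far, far, fx$model, far, far))
  expect_equal(attr(out2, "n_eliminated"), 6)
  # loosening upper bounds never shrinks the eliminated set
  loose <- fx$restraints; loose$upper <- loose$upper + 10
  out3 <- filter_encounter_satisfiable(loose, list(fx$model))
  expect_gte(attr(out3, "n_eliminated"), attr(out2, "n_eliminated"))
})

test_that("connectivity restraints carry the linker, ppant and active-site bounds", {
  rs <- add_connectivity_restraints(
    linker_a = list("A", 77, "CA"), linker_b = list("B", 94, "CA"),
    ppant_s = list("A", 37, "S43"), ppant_p = list("A", 37, "P"),
    his_ce1 = list("B", 223, "CE1"))
  expect_equal(rs$source, c("linker", "ppant_unfurl", "ppant_active_site"))
  expect_equal(rs$upper, c(59.5, 16.5, 8.0))
  expect_equal(rs$lower, c(0, 14.0, 0))
  m <- tiny_model(c(0, 0, 0), chain = "A", resno = 77, atom = "CA")
  expect_error(add_connectivity_restraints(
    linker_a = list("A", 77, "CA"), linker_b = list("B", 94, "CA"),
    ppant_s = list("A", 37, "S43"), ppant_p = list("A", 37, "P"),
    his_ce1 = list("B", 223, "CE1"), model = m), "not found")
})

test_that("violation reports cover both bound sides", {
  mk <- function(d) tiny_model(rbind(c(0, 0, 0), c(d, 0, 0)),
                               chain = c("A", "B"), resno = c(1, 2),
                               atom = c("N", "CB"))
  rs <- restraint_set(data.frame(chain_a = "A", resno_a = 1, atom_a = "N",
                                 chain_b = "B", resno_b = 2, atom_b = "CB",
                                 lower = c(0, 0, 14), upper = c(12, 12, 16.5)))
  ck10 <- check_violations(rs[1, ], mk(10))
  expect_equal(ck10$violation, 0)
  ck15 <- check_violations(rs[2, ], mk(15))
  expect_equal(ck15$violation, 3.0)
  ck13 <- check_violations(rs[3, ], mk(13))
  expect_equal(ck13$violation, 1.0)  # lower-bound side
})

test_that("tbl serialization encodes upper-bound-only restraints reversibly", {
  rs <- restraint_set(data.frame(
    chain_a = c("A", "A"), resno_a = c(3, 37), atom_a = c("N", "S43"),
    chain_b = c("B", "A"), resno_b = c(406, 37), atom_b = c("CB", "P"),
    lower = c(0, 14.0), upper = c(26.0, 16.5)))
  p <- tempfile(fileext = ".tbl")
  write_restraints(rs, p, "cns_tbl")
  txt <- grep("^assign", readLines(p), value = TRUE)
  expect_match(txt[1], "26 26 0$")        # d = upper, dminus = upper, dplus = 0
  expect_match(txt[2], "16.5 2.5 0$")     # bounds (14, 16.5)
  back <- read_restraints(p)
  expect_equal(back$upper, rs$upper)
  expect_equal(back$lower, rs$lower)
  expect_equal(back$atom_a, rs$atom_a)
  # JSON dialect keeps provenance columns
  pj <- tempfile(fileext = ".json")
  write_restraints(rs, pj, "json")
  expect_equal(jsonlite::read_json(pj, simplifyVector = TRUE)$upper, rs$upper)
})
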