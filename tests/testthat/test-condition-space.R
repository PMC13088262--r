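test_that("category and space constructors enforce their invariants", {
  expect_error(condition_category("x", "categorical", levels = "only_one"),
               ">= 2 levels")
  expect_error(condition_category("x", "categorical",
                                  levels = c("a", "a")), "duplicate")
  expect_error(condition_category("x", "numeric", range = c(5, 5)),
               "min must be < max")
  expect_error(condition_category("x", "numeric", range = c(1, 2),
                                  levels = c("a", "b")), "exactly one")
  expect_error(condition_space(list(
    condition_category("x", "categorical", levels = c("a", "b")),
    condition_category("x", "categorical", levels = c("c", "d")))),
    "unique")
  sp <- default_condition_space()
  expect_length(sp$categories, 10)
  expect_equal(space_dim(sp), 33)
  expect_equal(length(feature_names(sp)), space_dim(sp))
})

test_that("validate_scheme reports violations instead of raising", {
  sp <- mixed_space()
  ok <- validate_scheme(sp, scheme(cat = "level2", size = 600))
  expect_true(ok$ok)
  expect_length(ok$violations, 0)

  res <- validate_scheme(sp, scheme(cat = "level2"))
  expect_false(res$ok)
  expect_match(res$violations, "missing category", all = FALSE)

  res <- validate_scheme(sp, scheme(cat = "level2", size = 100))
  expect_false(res$ok)
  expect_match(res$violations, "out of range", all = FALSE)

  res <- validate_scheme(sp, scheme(cat = "no_such", size = 600))
  expect_false(res$ok)
  expect_match(res$violations, "undeclared level", all = FALSE)
})

test_that("encoding gives one-hot blocks plus min-max scaled numerics", {
  sp <- mixed_space()
  v <- encode_scheme(sp, scheme(cat = "level2", size = 600))
  expect_equal(unname(v), c(0, 1, 0, 0.5))
  expect_equal(unname(encode_scheme(sp, scheme(cat = "level1",
                                               size = 200))[4]), 0)
  expect_equal(unname(encode_scheme(sp, scheme(cat = "level3",
                                               size = 1000))[4]), 1)
  expect_error(encode_scheme(sp, scheme(cat = "level2", size = 50)),
               "out of range")
})

test_that("encode/decode round-trips 100 random schemes bijectively", {
  sp <- default_condition_space()
  schemes <- sample_schemes(sp, 100, seed = 7)
  for (s in schemes) {
    back <- decode_scheme(sp, encode_scheme(sp, s))
    a <- scheme_assignments(s)
    b <- scheme_assignments(back)
    expect_identical(names(a), names(b))
    for (nm in names(a)) {
      if (is.numeric(a[[nm]])) expect_equal(b[[nm]], a[[nm]],
                                            tolerance = 1e-9)
      else expect_identical(b[[nm]], a[[nm]])
    }
  }
  expect_error(decode_scheme(sp, numeric(5)), "length")
})

test_that("scheme JSON round-trips and is byte-stable with sorted keys", {
  sp <- mixed_space()
  s <- scheme(cat = "level3", size = 712.125)
  j1 <- scheme_to_json(s, sp)
  j2 <- scheme_to_json(s, sp)
  expect_identical(j1, j2)
  # byte-stability is independent of assignment order: keys sort per object
  s_rev <- scheme(size = 712.125, cat = "level3")
  expect_identical(scheme_to_json(s_rev, sp), j1)
  top <- regmatches(j1, gregexpr('"(assignments|format_version|meta|space_id)":',
                                 j1))[[1]]
  expect_identical(top, sort(top))
  back <- scheme_from_json(j1, sp)
  expect_identical(scheme_assignments(back)$cat, "level3")
  expect_equal(scheme_assignments(back)$size, 712.125)

  expect_error(scheme_from_json("{not json", sp), "parse error")
  bad <- '{"format_version":"1.0","space_id":"mixed2d","assignments":{"cat":"level1","unknown_thing":1,"size":500},"meta":{}}'
  expect_error(scheme_from_json(bad, sp), "unknown category")
  expect_error(scheme_from_json('{"format_version":"1.0"}', sp),
               "missing 'assignments'")
})

test_that("batches serialize as a JSON array of scheme codes", {
  sp <- tiny_cat_space()
  ss <- enumerate_space(sp)[1:3]
  txt <- schemes_to_json(ss, sp)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_length(parsed, 3)
  expect_identical(parsed[[1]]$space_id, "tiny3x3x3")
  back <- scheme_from_json(jsonlite::toJSON(parsed[[2]],
                                            auto_unbox = TRUE), sp)
  expect_identical(scheme_assignments(back), scheme_assignments(ss[[2]]))
})

test_that("uniform sampling is seeded, valid and level-balanced", {
  sp <- tiny_cat_space()
  expect_error(sample_schemes(sp, 0), ">= 1")
  a <- sample_schemes(sp, 25, seed = 42)
  b <- sample_schemes(sp, 25, seed = 42)
  expect_identical(lapply(a, scheme_assignments),
                   lapply(b, scheme_assignments))
  for (s in a) expect_true(validate_scheme(sp, s)$ok)

  big <- sample_schemes(sp, 10000, seed = 11)
  freq <- table(vapply(big, function(s) scheme_assignments(s)$alpha,
                       character(1)))
  # binomial: p = 1/3, se = sqrt(p(1-p)/n); all within 3 se
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_true(all(abs(freq / 10000 - 1 / 3) < 3 * se))
})

test_that("enumerate_space yields the exact lexicographic product", {
  sp2 <- condition_space(list(
    condition_category("p", "categorical", levels = c("p1", "p2", "p3")),
    condition_category("q", "categorical",
                       levels = c("q1", "q2", "q3", "q4"))))
  out <- enumerate_space(sp2)
  expect_length(out, 12)
  firsts <- vapply(out, function(s) scheme_assignments(s)$p, character(1))
  expect_identical(firsts, rep(c("p1", "p2", "p3"), each = 4))
  expect_identical(vapply(out[1:4], function(s) scheme_assignments(s)$q,
                          character(1)), c("q1", "q2", "q3", "q4"))

  one <- condition_space(list(
    condition_category("only", "categorical", levels = c("u", "v"))))
  res <- enumerate_space(one)
  expect_identical(vapply(res, function(s) scheme_assignments(s)$only,
                          character(1)), c("u", "v"))

  expect_error(enumerate_space(mixed_space()), "categorical")
  expect_error(enumerate_space(tiny_cat_space(), limit = 5), "limit")
})

test_that("space definition files round-trip through YAML", {
  sp <- default_condition_space()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_space(sp, path)
  back <- read_space(path)
  expect_equal(back$space_id, sp$space_id)
  expect_identical(category_names(back), category_names(sp))
  expect_equal(back$categories$particle_size$range, c(200, 1000))
  expect_identical(back$categories$functional_group$levels,
                   sp$categories$functional_group$levels)
})
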