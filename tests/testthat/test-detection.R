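test_that("aggregation translates boxes and applies IoU dedup", {
  sl <- toy_slide(w = 3000, h = 3000)
  # single patch, no overlaps: output = input translated
  pd <- data.frame(grade = "LSIL", confidence = 0.8,
                   x0 = 10, y0 = 10, x1 = 60, y1 = 60,
                   epithelium_score = 0.9, origin_x = 1024, origin_y = 768)
  ds <- aggregate_detections(sl, pd)
  expect_equal(nrow(ds$detections), 1)
  expect_equal(unlist(ds$detections[1, c("x0", "y0", "x1", "y1")]),
               c(x0 = 1034, y0 = 778, x1 = 1084, y1 = 828))

  # same cell in two overlapping patches, identical slide-level box
  pd2 <- data.frame(grade = "HSIL", confidence = c(0.7, 0.9),
                    x0 = c(800, 32), y0 = c(800, 32),
                    x1 = c(850, 82), y1 = c(850, 82),
                    epithelium_score = 0.9,
                    origin_x = c(0, 768), origin_y = c(0, 768))
  ds2 <- aggregate_detections(sl, pd2)
  expect_equal(nrow(ds2$detections), 1)
  expect_equal(ds2$detections$confidence, 0.9)

  # disjoint same-grade boxes (IoU 0) are both retained
  pd3 <- data.frame(grade = "HSIL", confidence = c(0.7, 0.9),
                    x0 = c(0, 500), y0 = 0, x1 = c(50, 550), y1 = 50,
                    epithelium_score = 0.9, origin_x = 0, origin_y = 0)
  expect_equal(nrow(aggregate_detections(sl, pd3)$detections), 2)

  # duplicates across DIFFERENT grades are never merged
  pd4 <- pd3
  pd4$grade <- c("HSIL", "LSIL")
  pd4$x0 <- c(0, 0); pd4$x1 <- c(50, 50)
  expect_equal(nrow(aggregate_detections(sl, pd4)$detections), 2)
})

test_that("aggregation never increases counts; boxes stay in bounds", {
  set.seed(5)
  sl <- toy_slide(w = 2000, h = 2000)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    pd <- data.frame(
      grade = sample(patch_grades(), n, replace = TRUE),
      confidence = runif(n),
      x0 = runif(n, 0, 900), y0 = runif(n, 0, 900),
      epithelium_score = runif(n),
      origin_x = sample(c(0, 768), n, replace = TRUE),
      origin_y = sample(c(0, 768), n, replace = TRUE))
    pd$x1 <- pd$x0 + runif(n, 5, 120)
    pd$y1 <- pd$y0 + runif(n, 5, 120)
    ds <- aggregate_detections(sl, pd, dedup_iou = 0.3)
    d <- ds$detections
    expect_lte(nrow(d), n)
    expect_true(all(d$x0 >= 0 & d$y0 >= 0 &
                      d$x1 <= sl$width_px & d$y1 <= sl$height_px))
    # no surviving same-grade pair above the dedup threshold
    for (g in unique(d$grade)) {
      dg <- d[d$grade == g, ]
      if (nrow(dg) > 1) {
        for (j in 1:(nrow(dg) - 1)) {
          ious <- box_iou(as.numeric(dg[j, c("x0", "y0", "x1", "y1")]),
                          as.matrix(dg[-seq_len(j), c("x0", "y0", "x1", "y1")]))
          expect_true(all(ious <= 0.3))
        }
      }
    }
  }
})

test_that("top_k_per_class sorts, caps, and tie-breaks by origin", {
  set.seed(8)
  ds <- toy_detection_set(rep("HSIL", 25), runif(25))
  top <- top_k_per_class(ds, k = 20)
  expect_equal(nrow(top[["HSIL"]]), 20)
  expect_equal(top[["HSIL"]]$confidence,
               sort(ds$detections$confidence, decreasing = TRUE)[1:20])
  expect_equal(nrow(top[["LSIL"]]), 0)

  ds3 <- toy_detection_set(rep("SCC", 3), c(0.5, 0.6, 0.7))
  expect_equal(nrow(top_k_per_class(ds3, 20)[["SCC"]]), 3)

  # equal confidences: ordered by (y, x) of the box origin
  d <- data.frame(grade = "AGC", confidence = 0.5,
                  x0 = c(300, 100), y0 = c(10, 10),
                  x1 = c(350, 150), y1 = c(60, 60), epithelium_score = 0.2)
  tie <- top_k_per_class(slide_detection_set(toy_slide(), d), 2)[["AGC"]]
  expect_equal(tie$x0, c(100, 300))
})

test_that("simulated detector honours its profile statistics", {
  # NILM latent slide, zero false-positive rate -> empty set
  prof0 <- detector_profile(fp_rate = 0)
  sl <- toy_slide(grade = "NILM")
  latent <- list(slide = sl, cells = data.frame(grade = character(0),
                                                cx = numeric(0),
                                                cy = numeric(0)))
  set.seed(1)
  expect_equal(nrow(detect_simulated(latent, prof0)$detections), 0)

  # identity confusion: every HSIL cell observed as HSIL
  prof_id <- detector_profile(confusion = diag(6) + 0, fp_rate = 0)
  dimnames(prof_id$confusion) <- list(patch_grades(), patch_grades())
  latent_h <- list(slide = sl,
                   cells = data.frame(grade = rep("HSIL", 30),
                                      cx = runif(30, 100, 3000),
                                      cy = runif(30, 100, 3000)))
  set.seed(2)
  out <- detect_simulated(latent_h, prof_id)
  expect_true(all(out$detections$grade == "HSIL"))

  # Poisson rate recovery: lambda = 5 over 400 seeded slides
  rates <- matrix(0, 5, 6, dimnames = list(slide_grades(), patch_grades()))
  rates["LSIL", "LSIL"] <- 5
  cfg <- cohort_config(400, prevalences = c("NILM" = 0, "ASC-US" = 0,
                                            "LSIL" = 1, "HSIL+" = 0,
                                            "AGC" = 0),
                       profile = detector_profile(rates = rates,
                                                  fp_rate = 0),
                       seed = 33)
  co <- generate_cohort(cfg)
  counts <- vapply(co$sets, function(s) nrow(s$detections), numeric(1))
  se <- sqrt(5 / 400)
  expect_lt(abs(mean(counts) - 5), 3 * se)

  # determinism under a fixed seed
  set.seed(9)
  a <- detect_simulated(latent_h, prof0)
  set.seed(9)
  b <- detect_simulated(latent_h, prof0)
  expect_identical(a$detections, b$detections)
  expect_error(detect_simulated(list(), prof0), "malformed")
})

test_that("detection tables round-trip through CSV and JSON", {
  co <- generate_cohort(cohort_config(5, seed = 4))
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_detections(co$sets, path, format = fmt)
    slides <- data.frame(
      slide_id = vapply(co$sets, function(s) s$slide$slide_id, character(1)),
      width_px = 5000, height_px = 5000, true_grade = co$truth)
    back <- read_detections(path, slides, format = fmt)
    expect_length(back, 5)
    for (i in 1:5) {
      expect_equal(nrow(back[[i]]$detections), nrow(co$sets[[i]]$detections))
      expect_equal(back[[i]]$detections$confidence,
                   co$sets[[i]]$detections$confidence, tolerance = 1e-12)
    }
  }
})
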