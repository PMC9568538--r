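test_that("toy backbones built from the same seed agree on every input", {
    bb1 <- toyBackbone(seed = 9, inputSide = 32L, featureDim = 20L)
    bb2 <- toyBackbone(seed = 9, inputSide = 32L, featureDim = 20L)
    bb3 <- toyBackbone(seed = 10, inputSide = 32L, featureDim = 20L)
    for (s in 1:5) {
        img <- randomFace(s, 40L)
        expect_identical(extractPatchFeatures(img, bb1),
                         extractPatchFeatures(img, bb2))
    }
    img <- randomFace(1, 40L)
    expect_false(identical(extractPatchFeatures(img, bb1),
                           extractPatchFeatures(img, bb3)))
})

test_that("toy backbone zero-image response matches the frozen vector", {
    bb <- toyBackbone(seed = 123L, inputSide = 32L, featureDim = 8L, grid = 4L)
    v <- extractPatchFeatures(array(0, c(32, 32, 3)), bb)
    expect_equal(v, c(-0.032178145608, 0.147695561590, -0.165263108328,
                      -0.043655233522, 0.045714323359, -0.160380655174,
                      0.027955500325, 0.185609749874), tolerance = 1e-10)
    # nonconstant map: saturated image gives a different vector
    expect_false(identical(v, extractPatchFeatures(array(255, c(32, 32, 3)), bb)))
})

test_that("toy backbone distinguishes images differing in one pooled cell", {
    bb <- toyBackbone(seed = 5, inputSide = 32L, featureDim = 16L, grid = 4L)
    differing <- 0L
    for (s in 1:100) {
        img <- randomFace(1000 + s, 32L)
        img2 <- img
        img2[1:8, 1:8, ] <- 255 - img2[1:8, 1:8, ]   # one 4x4-grid cell
        v1 <- bb@extract(img)
        v2 <- bb@extract(img2)
        if (!isTRUE(all.equal(v1, v2))) differing <- differing + 1L
    }
    expect_identical(differing, 100L)
})

test_that("extraction sees only the resized patch", {
    bb <- toyBackbone(seed = 2, inputSide = 64L, featureDim = 12L)
    strip <- randomFace(11, 64L)[1:16, , ]            # 16 x 64 strip
    pre <- resizeFace(strip, 64L)
    expect_identical(extractPatchFeatures(strip, bb),
                     extractPatchFeatures(pre, bb))
    expect_identical(extractPatchFeatures(strip, bb),
                     extractPatchFeatures(strip, bb))
})

test_that("a backbone violating its output-length contract is caught", {
    bad <- new("Backbone", name = "bad", inputSide = 32L, featureDim = 10L,
               extract = function(img) numeric(3))
    expect_error(extractPatchFeatures(randomFace(1, 32L), bad),
                 class = "painstrips_contract_error")
})

test_that("extractAll concatenates 22 blocks, whole face last", {
    bb <- toyBackbone(seed = 3, inputSide = 32L, featureDim = 25L)
    face <- randomFace(12)
    v <- extractAll(face, bb)
    expect_length(v, 22L * 25L)
    bm <- blockMap(v)
    expect_identical(nrow(bm), 22L)
    expect_identical(bm$block[22L], "whole")
    expect_identical(bm$start, (0:21) * 25L + 1L)
    expect_identical(bm$end, (1:22) * 25L)
    # block/whole consistency with per-strip extraction
    ps <- makeBlinds(face)
    for (k in c(1L, 7L, 21L)) {
        expect_identical(v[bm$start[k]:bm$end[k]],
                         extractPatchFeatures(strips(ps)[[k]], bb))
    }
    expect_identical(v[bm$start[22]:bm$end[22]],
                     extractPatchFeatures(face, bb))
})

test_that("a constant face gives 22 identical blocks", {
    bb <- toyBackbone(seed = 4, inputSide = 32L, featureDim = 10L)
    v <- extractAll(array(90, c(224, 224, 3)), bb)
    m <- matrix(v, nrow = 10L)
    expect_true(all(apply(m, 1L, function(r) max(abs(r - r[1]))) < 1e-12))
})

test_that("content changes inside one finest strip touch only the expected blocks", {
    bb <- toyBackbone(seed = 6, inputSide = 32L, featureDim = 10L)
    face <- randomFace(13)
    v1 <- extractAll(face, bb)
    face2 <- face
    face2[1:28, , ] <- 255 - face2[1:28, , ]   # strictly inside top strip of every scale
    v2 <- extractAll(face2, bb)
    bm <- blockMap(v1)
    changed <- vapply(seq_len(nrow(bm)), function(k) {
        !identical(v1[bm$start[k]:bm$end[k]], v2[bm$start[k]:bm$end[k]])
    }, logical(1))
    expect_identical(bm$block[changed],
                     c("s2_1", "s4_1", "s7_1", "s8_1", "whole"))
})

test_that("feature sets build correctly and round-trip through CSV bit-exactly", {
    bb <- toyBackbone(seed = 8, inputSide = 32L, featureDim = 6L)
    lv <- painClassLabels()
    faces <- lapply(1:4, function(s) randomFace(s))
    cls <- factor(lv, levels = lv)
    fs <- buildFeatureSet(faces, cls, bb, ids = sprintf("im%d", 1:4))
    X <- featureMatrix(fs)
    expect_identical(dim(X), c(4L, 132L))
    expect_identical(painClass(fs), cls)
    expect_identical(rownames(X), sprintf("im%d", 1:4))

    tmp <- withr::local_tempfile(fileext = ".csv")
    writeFeatureCSV(fs, tmp)
    fs2 <- readFeatureCSV(tmp)
    expect_identical(unname(featureMatrix(fs2)), unname(X))
    expect_identical(as.character(painClass(fs2)), as.character(cls))
})
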