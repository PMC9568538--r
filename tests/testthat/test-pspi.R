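test_that("pspiScore follows the PSPI definition on known cases", {
    expect_identical(pspiScore(0, 0, 0, 0, 0, 0), 0L)
    expect_identical(pspiScore(5, 5, 0, 5, 0, 1), 16L)  # maximum attainable
    expect_identical(pspiScore(2, 1, 3, 2, 4, 0), 9L)   # 2 + 3 + 4 + 0
    expect_identical(pspiScore(c(0, 5), c(0, 5), c(0, 0), c(0, 5), c(0, 0), c(0, 1)),
                     c(0L, 16L))
})

test_that("pspiScore validates each action unit by name", {
    expect_error(pspiScore(6, 0, 0, 0, 0, 0), "au4",
                 class = "painstrips_validation_error")
    expect_error(pspiScore(0, 0, 0, 0, 0, 2), "au43",
                 class = "painstrips_validation_error")
    expect_error(pspiScore(0, -1, 0, 0, 0, 0), "au6",
                 class = "painstrips_validation_error")
    expect_error(pspiScore(0, 0.5, 0, 0, 0, 0), "au6",
                 class = "painstrips_validation_error")
})

test_that("pspiScore is monotone non-decreasing in every action unit", {
    withr::with_seed(7, {
        for (rep in 1:50) {
            au <- c(sample(0:5, 5, TRUE), sample(0:1, 1))
            base <- do.call(pspiScore, as.list(au))
            for (f in 1:6) {
                up <- au
                lim <- if (f == 6) 1L else 5L
                if (up[f] < lim) up[f] <- up[f] + 1L
                expect_gte(do.call(pspiScore, as.list(up)), base)
            }
        }
    })
})

test_that("pspiGroup partitions all 17 scores into the four classes", {
    grp <- pspiGroup(0:16)
    expect_false(anyNA(grp))
    expect_identical(levels(grp), painClassLabels())
    expect_identical(as.integer(table(grp)), c(1L, 1L, 2L, 13L))
    expect_identical(as.character(pspiGroup(0)), "PSPI=0")
    expect_identical(as.character(pspiGroup(3)), "2<=PSPI<=3")
    expect_identical(as.character(pspiGroup(15)), "PSPI>3")
    expect_error(pspiGroup(-1), class = "painstrips_validation_error")
    expect_error(pspiGroup(17), class = "painstrips_validation_error")
})

test_that("every valid AU combination maps to exactly one class", {
    g <- expand.grid(au4 = 0:5, au6 = 0:5, au7 = 0:5, au9 = 0:5,
                     au10 = 0:5, au43 = 0:1)
    s <- pspiScore(g$au4, g$au6, g$au7, g$au9, g$au10, g$au43)
    expect_true(all(s >= 0 & s <= 16))
    cls <- pspiGroup(s)
    expect_false(anyNA(cls))
    expect_identical(max(s), 16L)
})

test_that("balanceUndersample reproduces the published group sizes", {
    counts <- c(40029L, 2909L, 3763L, 1697L)
    targets <- c(2483L, 2909L, 3763L, 1697L)
    lv <- painClassLabels()
    labels <- data.frame(
        id = sprintf("f%05d", seq_len(sum(counts))),
        class_label = rep(lv, times = counts),
        stringsAsFactors = FALSE)
    out <- balanceUndersample(labels, targets, seed = 5)
    expect_identical(as.integer(table(factor(out$class_label, levels = lv))),
                     targets)
    expect_identical(nrow(out), 10852L)
    expect_true(all(out$id %in% labels$id))
})

test_that("balanceUndersample is deterministic, identity at full targets, and validates", {
    lv <- painClassLabels()
    withr::with_seed(3, {
        labels <- data.frame(
            id = sprintf("f%03d", 1:80),
            class_label = sample(rep(lv, times = c(30, 20, 20, 10))),
            stringsAsFactors = FALSE)
    })
    a <- balanceUndersample(labels, c(15L, 20L, 12L, 10L), seed = 42)
    b <- balanceUndersample(labels, c(15L, 20L, 12L, 10L), seed = 42)
    expect_identical(a, b)
    expect_true(all(a$id %in% labels$id))
    # classes at or below target kept whole, in original order
    expect_identical(balanceUndersample(labels, c(30L, 20L, 20L, 10L), 1),
                     labels)
    expect_error(balanceUndersample(labels, c(31L, 20L, 20L, 10L), 1),
                 "PSPI=0", class = "painstrips_validation_error")
})

test_that("AU tables round-trip and enforce the column dialect", {
    tmp <- withr::local_tempfile(fileext = ".csv")
    au <- data.frame(id = c("a", "b"), au4 = c(2L, 0L), au6 = c(1L, 0L),
                     au7 = c(3L, 0L), au9 = c(2L, 0L), au10 = c(4L, 0L),
                     au43 = c(0L, 1L))
    write.csv(au, tmp, row.names = FALSE)
    tab <- readAUTable(tmp)
    lab <- labelAUTable(tab)
    expect_identical(lab$pspi, c(9L, 1L))
    expect_identical(lab$class_label, c("PSPI>3", "PSPI=1"))
    expect_identical(lab$class_index, c(3L, 1L))
    freq <- classFrequency(lab)
    expect_identical(freq$count[freq$class_label == "Total"], 2L)
    expect_identical(sum(freq$count[freq$class_label != "Total"]), 2L)

    bad <- au[setdiff(names(au), "au10")]
    write.csv(bad, tmp, row.names = FALSE)
    expect_error(readAUTable(tmp), "au10",
                 class = "painstrips_validation_error")
    expect_error(readAUTable("no/such/file.csv"),
                 class = "painstrips_io_error")
})
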