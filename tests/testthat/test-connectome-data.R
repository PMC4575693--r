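test_that("connectivity matrices round-trip through TSV with statuses intact", {
  m <- rbind(A = c(NA, 2, NA), B = c(0, NA, 1), C = c(3, NA, NA))
  colnames(m) <- rownames(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  connectopred:::write_matrix_tsv(m, path)
  tab <- load_connectivity(path)
  expect_equal(nrow(tab), 4)
  key <- paste(tab$source, tab$target)
  expect_equal(tab$status[key == "A B"], "intermediate")
  expect_equal(tab$status[key == "B A"], "absent")
  expect_equal(tab$status[key == "C A"], "dense")
  expect_false("A C" %in% key)  # NA cell stays unknown

  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity(tab, path2)
  tab2 <- load_connectivity(path2)
  expect_identical(tab2[order(tab2$source, tab2$target), ],
                   tab[order(tab$source, tab$target), ])
})

test_that("all-NA matrices load as an empty record set", {
  m <- matrix(NA, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  path <- withr::local_tempfile(fileext = ".tsv")
  connectopred:::write_matrix_tsv(m, path)
  tab <- load_connectivity(path)
  expect_equal(nrow(tab), 0)
  expect_equal(unname(status_counts(tab)["unknown"]), 6)
})

test_that("malformed connectivity input is rejected with a located error", {
  m <- rbind(A = c(NA, "7"), B = c("0", NA))
  colnames(m) <- rownames(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  connectopred:::write_matrix_tsv(m, path)
  expect_error(load_connectivity(path), "row A, column B")

  expect_error(projection_table(
    data.frame(source = "A", target = "A", status = "dense"), c("A", "B")),
    "self-projection")
  expect_error(projection_table(
    data.frame(source = c("A", "A"), target = c("B", "B"),
               status = c("dense", "absent")), c("A", "B")),
    "duplicate records")
  expect_error(projection_table(
    data.frame(source = "A", target = "Z", status = "dense"), c("A", "B")),
    "outside the universe")
})

test_that("status counts partition all ordered pairs of distinct areas", {
  x <- synthetic_connectome(generator_config(n_areas = 16, seed = 7))
  sc <- status_counts(x$table)
  n <- nrow(x$parcellation$areas)
  expect_equal(sum(sc), n * (n - 1))
  scb <- status_counts(binarize(x$table))
  expect_equal(sum(scb), n * (n - 1))
  expect_equal(unname(scb["unknown"]), unname(sc["unknown"]))
  expect_equal(unname(scb["absent"]), unname(sc["absent"]))
  expect_equal(unname(scb["present"]),
               unname(sc["sparse"] + sc["intermediate"] + sc["dense"]))
})

test_that("binarize maps strengths to present and fixes absent/unknown", {
  tab <- projection_table(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
               status = c("dense", "sparse", "absent")), c("A", "B", "C", "D"))
  b <- binarize(tab)
  expect_equal(sort(unique(b$status)), c("absent", "present"))
  expect_identical(binarize(b), b)  # idempotent
})

test_that("adjacency edits apply symmetrically and are idempotent", {
  nm <- c("17", "CGp", "RS", "18", "20a")
  adj <- matrix(FALSE, 5, 5, dimnames = list(nm, nm))
  adj["17", "CGp"] <- adj["CGp", "17"] <- TRUE
  adj["17", "RS"] <- adj["RS", "17"] <- TRUE
  adj["17", "18"] <- adj["18", "17"] <- TRUE
  adj["RS", "20a"] <- adj["20a", "RS"] <- TRUE
  parc <- parcellation(data.frame(name = nm), adj)

  edits <- list(list(op = "remove", a = "17", b = "CGp"),
                list(op = "add", a = "18", b = "20a"))
  out <- apply_adjacency_edits(parc, edits)
  expect_false(out$adjacency["17", "CGp"])
  expect_false(out$adjacency["CGp", "17"])
  expect_true(out$adjacency["18", "20a"])
  expect_true(out$adjacency["20a", "18"])
  expect_identical(apply_adjacency_edits(parc, list())$adjacency,
                   parc$adjacency)
  expect_warning(apply_adjacency_edits(out, edits[2]), "no-op")
  expect_error(apply_adjacency_edits(parc,
    list(list(op = "add", a = "17", b = "nope"))), "unknown area")
})

test_that("the default cat adjacency edit list is complete and readable as JSON", {
  edits <- cat_adjacency_edits()
  expect_length(edits, 12)
  expect_equal(sum(vapply(edits, function(e) e$op == "remove", NA)), 2)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(edits, path, auto_unbox = TRUE)
  expect_identical(read_adjacency_edits(path), edits)
})

test_that("parcellation constructor enforces symmetry, uniqueness and type range", {
  nm <- c("A", "B")
  adj <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, dimnames = list(nm, nm))
  expect_error(parcellation(data.frame(name = nm), adj), "symmetric")
  expect_error(parcellation(data.frame(name = c("A", "A")),
                            diag(2) == 1), "duplicate")
  adj2 <- matrix(FALSE, 2, 2, dimnames = list(nm, nm))
  expect_error(parcellation(data.frame(name = nm, structural_type = c(1, 6)),
                            adj2), "1..5")
})
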