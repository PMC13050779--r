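test_that("parcel series round-trip through CSV and TSV at full precision", {
  x <- parcel_ts(matrix(rnorm(46 * 40), 46, 40),
                 sprintf("p%02d", 1:46), subject_id = "s03",
                 condition = "task")
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parcel_ts(x, path)
    y <- read_parcel_ts(path, subject_id = "s03", condition = "task")
    expect_identical(unname(y$values), unname(x$values))
    expect_identical(y$parcel_ids, x$parcel_ids)
  }
})

test_that("reading malformed or mismatched files fails informatively", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("parcel_id,t1,t2", "p1,1.5,oops", "p2,2,3"), path)
  expect_error(read_parcel_ts(path), class = "birnn_parse_error")
  expect_error(read_parcel_ts(path, parcel_ids = c("a", "b")),
               class = "birnn_parse_error")
  writeLines(c("parcel_id,t1,t2", "p1,1,2", "p2,2,3"), path)
  expect_error(read_parcel_ts(path, parcel_ids = c("p2", "p1")),
               class = "birnn_shape_error")
  expect_error(read_parcel_ts("no/such/file.csv"), class = "birnn_io_error")
  expect_error(parcel_ts(matrix(1:4, 2, 2), c("a", "b", "c")),
               class = "birnn_shape_error")
  expect_error(parcel_ts(matrix(1:2, 2, 1), c("a", "b")),
               class = "birnn_shape_error")
})

test_that("voxel-to-parcel aggregation is the plain per-time-point mean", {
  v <- matrix(c(1, 3), 2, 1)
  v <- cbind(v, v) # T = 2
  out <- aggregate_voxels_to_parcels(v, c("A", "A"))
  expect_equal(unname(out$values["A", ]), c(2, 2))

  single <- matrix(rnorm(10), 1, 10)
  out1 <- aggregate_voxels_to_parcels(single, "B")
  expect_equal(unname(out1$values[1, ]), single[1, ])

  set.seed(42)
  vox <- matrix(rnorm(6 * 9), 6, 9)
  map <- c("p1", "p2", "p1", "p2", "p2", "p1")
  agg <- aggregate_voxels_to_parcels(vox, map)
  for (p in c("p1", "p2")) {
    oracle <- apply(vox[map == p, ], 2, mean) # brute-force per time point
    expect_equal(unname(agg$values[p, ]), oracle)
  }
  expect_error(aggregate_voxels_to_parcels(vox, c(map[-6], NA)),
               class = "birnn_empty_parcel_error")
})

test_that("network projection encodes the assignment with row-normalized W_in", {
  m <- data.frame(parcel_id = c("p1", "p2", "p3"),
                  network = c("DMN", "DMN", "TPN"))
  pr <- network_projection(m, network_names = c("DMN", "TPN"))
  expect_equal(unname(pr$W_in), rbind(c(0.5, 0.5, 0), c(0, 0, 1)))
  expect_true(all(colSums(pr$W_in != 0) == 1)) # one network per parcel
  expect_equal(unname(rowSums(pr$W_in)), c(1, 1))
  expect_equal(unname(pr$W_out_pattern),
               cbind(c(1, 1, 0), c(0, 0, 1)))

  expect_error(network_projection(
    data.frame(parcel_id = "p1", network = "Imaginary")),
    class = "birnn_label_error")
  expect_error(network_projection(
    data.frame(parcel_id = c("p1", "p1"), network = c("DMN", "SN"))),
    class = "birnn_assignment_error")
  expect_error(network_projection(
    data.frame(parcel_id = c("p1", "p2"), network = c("DMN", NA))),
    class = "birnn_assignment_error")
})

test_that("the packaged default atlas yields the study-scale 4 x 46 projection", {
  pr <- default_projection()
  expect_equal(dim(pr$W_in), c(4, 46))
  expect_equal(dim(pr$W_out_pattern), c(46, 4))
  expect_equal(pr$network_names, c("DMN", "TPN", "SN", "Other"))
  # all-ones parcel vector maps to all-ones network vector
  expect_equal(unname(as.numeric(pr$W_in %*% rep(1, 46))), rep(1, 4))
})

test_that("parcel-to-network aggregation equals per-network means", {
  pr <- tiny_projection(6, 2)
  const <- parcel_ts(matrix(3.7, 6, 5), pr$parcel_ids)
  expect_equal(unname(aggregate_parcels_to_networks(const, pr)),
               matrix(3.7, 2, 5), ignore_attr = TRUE)

  one <- synthetic_membership(4, "DMN")
  x <- parcel_ts(matrix(rnorm(4 * 7), 4, 7), one$parcel_ids)
  expect_equal(as.numeric(aggregate_parcels_to_networks(x, one)),
               colMeans(x$values))

  set.seed(7)
  x2 <- parcel_ts(matrix(rnorm(6 * 8), 6, 8), pr$parcel_ids)
  agg <- aggregate_parcels_to_networks(x2, pr)
  for (k in 1:2) { # brute-force oracle
    members <- which(pr$net_index == k)
    expect_equal(unname(agg[k, ]), colMeans(x2$values[members, ]))
  }

  bad <- parcel_ts(x2$values, rev(pr$parcel_ids))
  expect_error(aggregate_parcels_to_networks(bad, pr),
               class = "birnn_alignment_error")
})

test_that("aggregation commutes with time slicing", {
  pr <- tiny_projection(6, 2)
  x <- parcel_ts(matrix(rnorm(6 * 20), 6, 20), pr$parcel_ids)
  full_then_cut <- aggregate_parcels_to_networks(x, pr)[, 1:9]
  cut_then_agg <- aggregate_parcels_to_networks(
    parcel_ts(x$values[, 1:9], pr$parcel_ids), pr)
  expect_equal(full_then_cut, cut_then_agg)
})

test_that("SNR maps to the inverse regularization constant 1/snr^2", {
  expect_equal(round(inverse_regularization_from_snr(3), 3), 0.111)
  expect_equal(inverse_regularization_from_snr(1), 1)
  expect_equal(inverse_regularization_from_snr(2), 0.25)
  expect_error(inverse_regularization_from_snr(0), class = "birnn_domain_error")
  expect_error(inverse_regularization_from_snr(-2), class = "birnn_domain_error")
})

test_that("an events table segments a session into condition blocks", {
  x <- parcel_ts(matrix(rnorm(3 * 1000), 3, 1000), c("a", "b", "c"),
                 sampling_rate = 100)
  ev <- data.frame(onset_s = c(0, 5), offset_s = c(4, 10),
                   label = c("rest", "task"))
  seg <- segment_by_events(x, ev)
  expect_equal(seg$condition, c("rest", "task"))
  expect_equal(ncol(seg$series[[1]]$values), 400)
  expect_equal(seg$series[[2]]$condition, "task")
  expect_equal(seg$series[[2]]$values[, 1], x$values[, 501])
})
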