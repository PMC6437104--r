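# WAV, data-matrix and model file round trips.

test_that("WAV round trip is lossless up to one quantization step", {
  path <- withr::local_tempfile(fileext = ".wav")
  x <- make_tone(440, 0.2)
  write_wav(audio_record(x, FS), path)
  rec <- read_wav(path)
  expect_equal(rec$sample_rate_hz, FS)
  expect_lt(max(abs(rec$samples - x)), 2^-15)
})

test_that("all-zero and full-scale PCM values decode exactly", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_record(numeric(FS), FS), path)
  rec <- read_wav(path)
  expect_length(rec$samples, FS)
  expect_true(all(rec$samples == 0))

  # full-scale square wave stored as +/-32767: integer-scaling oracle says
  # the decoded amplitudes are exactly +/-(32767/32768)
  pcm <- as.integer(rep(c(32767, -32767), each = 50, times = 10))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(16000L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  close(con)
  rec <- read_wav(path)
  expect_true(all(abs(rec$samples) == 32767 / 32768))
})

test_that("stereo WAV input is downmixed by channel averaging", {
  path <- withr::local_tempfile(fileext = ".wav")
  left <- as.integer(round(make_tone(200, 0.05, 8000, 0.5) * 32767))
  right <- as.integer(round(make_tone(200, 0.05, 8000, 0.25) * 32767))
  inter <- as.vector(rbind(left, right))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(inter)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")      # stereo
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(inter)), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  rec <- read_wav(path)
  expect_equal(rec$samples, (left + right) / 2 / 32768, tolerance = 1e-12)
})

test_that("non-WAV input and compressed codecs are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".wav")
  writeLines("definitely not audio", path)
  expect_error(read_wav(path), "RIFF")
  # a WAV header claiming an mu-law codec (format tag 7)
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(36L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(7L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(0L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_wav(path), "codec|format tag")
})

test_that("data matrix round trips losslessly and enforces its schema", {
  dm <- synthetic_data_matrix(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_data_matrix(dm, path)
  back <- read_data_matrix(path)
  expect_equal(back, dm, tolerance = 1e-12)

  empty <- dm[0, ]
  write_data_matrix(empty, path)
  expect_equal(nrow(read_data_matrix(path)), 0)

  bad <- dm; bad$health_status[1] <- 3L
  expect_error(write_data_matrix(bad, path), "health_status")

  extra <- dm; extra$mystery <- 1
  utils::write.csv(extra, path, row.names = FALSE)
  expect_error(read_data_matrix(path), "mystery")
})

test_that("model files round trip with identical predictions", {
  blobs <- make_blobs(20)
  mlp <- mlp_train(mlp_config(p = 2, max_epochs = 50), blobs$X, blobs$y)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(mlp, path)
  back <- load_model(path)
  probe <- matrix(stats::rnorm(20), 10, 2)
  expect_identical(mlp_forward(back, probe), mlp_forward(mlp, probe))
  expect_equal(back$W, mlp$W)

  rbfn <- rbfn_train(rbfn_config(input_size = 2, n_centers = 4,
                                 supervised_epochs = 50), blobs$X, blobs$y)
  save_model(rbfn, path)
  back <- load_model(path)
  expect_identical(rbfn_forward(back, probe), rbfn_forward(rbfn, probe))
  expect_equal(back$centers, rbfn$centers)
  expect_equal(back$widths, rbfn$widths)
})

test_that("truncated or version-mismatched model files fail loudly", {
  blobs <- make_blobs(10)
  mlp <- mlp_train(mlp_config(p = 2, max_epochs = 10), blobs$X, blobs$y)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(mlp, path)
  txt <- readChar(path, file.size(path))
  writeChar(substr(txt, 1, nchar(txt) %/% 2), path, eos = NULL)
  expect_error(load_model(path), "corrupt|integrity")

  save_model(mlp, path)
  txt <- readChar(path, file.size(path))
  writeChar(sub('"format_version":"1.0"', '"format_version":"9.9"', txt,
                fixed = TRUE), path, eos = NULL)
  expect_error(load_model(path), "version")
})
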