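test_that("calibration CSV writes and re-reads losslessly", {
    d <- simulateBlackbodyCampaign(SensorSimConfig(seed = 11))
    f <- withr::local_tempfile(fileext = ".csv")
    writeCalibrationCsv(d, f)
    expect_length(readLines(f), nRecords(d) + 1L)   # header + rows
    back <- readCalibrationCsv(f)
    expect_equal(calRecords(back)$frame_id, calRecords(d)$frame_id)
    expect_lt(max(abs(calRecords(back)$dl - calRecords(d)$dl)), 1e-6)
    expect_lt(max(abs(calRecords(back)$tc - calRecords(d)$tc)), 1e-6)
    expect_lt(max(abs(calRecords(back)$tbb - calRecords(d)$tbb)), 1e-6)

    ## empty dataset -> header-only file
    e <- CalibrationDataset(dl = numeric(), tc = numeric(), tbb = numeric())
    writeCalibrationCsv(e, f)
    expect_length(readLines(f), 1L)
})

test_that("calibration CSV reader preserves order and reports bad input", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("frame_id,dl_mean,sensor_temp_c,blackbody_temp_c,extra",
                 "a,7000,20,25,x", "b,7100.5,21,30,y", "c,7200,22,35,z"), f)
    d <- readCalibrationCsv(f)
    expect_equal(calRecords(d)$frame_id, c("a", "b", "c"))
    expect_equal(calRecords(d)$dl, c(7000, 7100.5, 7200))

    writeLines(c("frame_id,dl_mean,sensor_temp_c", "a,7000,20"), f)
    expect_error(readCalibrationCsv(f), "blackbody_temp_c")

    writeLines(c("frame_id,dl_mean,sensor_temp_c,blackbody_temp_c",
                 "a,7000,20,25", "b,oops,21,30"), f)
    expect_error(readCalibrationCsv(f), "row 2")
})

test_that("thermal frames round-trip through 16-bit TIFF plus sidecar", {
    img <- withr::local_tempfile(fileext = ".tif")
    side <- withr::local_tempfile(fileext = ".json")
    px <- matrix(sample.int(16383, 16), 4)
    writeThermalFrame(ThermalFrame(px, 25.0, "t"), img, side)
    fr <- readThermalFrame(img, side)
    expect_equal(pixelMatrix(fr), px)
    expect_equal(sensorTemp(fr), 25.0)

    ## multi-channel image is rejected
    rgb <- withr::local_tempfile(fileext = ".tif")
    tiff::writeTIFF(array(runif(4 * 4 * 3), c(4, 4, 3)), rgb)
    expect_error(readThermalFrame(rgb, side), "single-channel")

    ## sidecar without the sensor temperature is rejected
    bad <- withr::local_tempfile(fileext = ".json")
    writeLines('{"exposure": 1}', bad)
    expect_error(readThermalFrame(img, bad), "sensor_temperature_c")
})

test_that("ROI mean equals hand values and the brute-force oracle", {
    fr <- ThermalFrame(matrix(1000, 8, 8), 20)
    expect_equal(extractRoiMean(fr, RoiSelection(2, 5, 1, 7)), 1000)

    fr2 <- ThermalFrame(matrix(c(10, 30, 20, 40), 2), 20)
    expect_equal(extractRoiMean(fr2, RoiSelection(0, 2, 0, 2)), 25)

    set.seed(42)
    px <- matrix(runif(400, 0, 16000), 20)
    fr3 <- ThermalFrame(px, 20)
    for (k in 1:5) {
        r0 <- sample(0:15, 1); r1 <- r0 + sample(1:4, 1)
        c0 <- sample(0:15, 1); c1 <- c0 + sample(1:4, 1)
        expect_equal(extractRoiMean(fr3, RoiSelection(r0, r1, c0, c1)),
                     loopRoiMean(px, r0, r1, c0, c1))
    }
    expect_error(RoiSelection(3, 3, 0, 2), "non-empty")
    expect_error(extractRoiMean(fr2, RoiSelection(0, 5, 0, 2)), "bounds")
})

test_that("temperature maps round-trip through 32-bit float TIFF", {
    f <- withr::local_tempfile(fileext = ".tif")
    z <- TemperatureMap(matrix(0, 2, 2), "m")
    writeTemperatureMap(z, f)
    expect_equal(temps(readTemperatureMap(f)), matrix(0, 2, 2))

    one <- TemperatureMap(matrix(29.7, 2, 3), "m")
    writeTemperatureMap(one, f)
    expect_lt(max(abs(temps(readTemperatureMap(f)) - 29.7)), 1e-5)

    set.seed(7)
    m <- TemperatureMap(matrix(runif(64 * 64, -20, 80), 64), "m")
    writeTemperatureMap(m, f)
    expect_lt(max(abs(temps(readTemperatureMap(f)) - temps(m))), 1e-5)
})

test_that("container classes enforce their invariants", {
    expect_error(ThermalFrame(matrix(-5, 4, 4), 20), "0, 65535")
    expect_error(ThermalFrame(matrix(1, 1, 4), 20), "2x2")
    expect_error(CalibrationDataset(dl = 70000, tc = 20, tbb = 30),
                 "0, 65535")
    expect_error(CalibrationDataset(dl = 7000, tc = 20, tbb = 300),
                 "plausible range")
    expect_error(TemperatureMap(matrix(c(1, NA, 2, 3), 2)), "finite")
})
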