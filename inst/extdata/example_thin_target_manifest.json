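{
  "_comment": "Example manifest for a lensless three-distance stack of an optically thin resolution phase target (561 nm, 2.4 um pixels, distances 4.5/6.5/8.5 mm, 8-bit camera). Point the paths at your own downloaded or acquired frames; distances and wavelengths are in meters.",
  "pixel_pitch_m": 2.4e-06,
  "multiplex_mode": "distance",
  "frames": [
    { "path": "thin_target_z4p5mm.tif", "distance_m": 0.0045, "wavelength_m": 5.61e-07, "dtype": "uint8", "scale": 1, "offset": 0 },
    { "path": "thin_target_z6p5mm.tif", "distance_m": 0.0065, "wavelength_m": 5.61e-07, "dtype": "uint8", "scale": 1, "offset": 0 },
    { "path": "thin_target_z8p5mm.tif", "distance_m": 0.0085, "wavelength_m": 5.61e-07, "dtype": "uint8", "scale": 1, "offset": 0 }
  ],
  "camera": { "bit_depth": 8 },
  "acquisition": { "irradiance_uW_cm2": 2.71, "exposure_s": 0.01 }
}
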