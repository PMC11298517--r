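# Default acquisition configuration: five excitation lasers with their
# matched emission filters. Exposure 104 ms everywhere except 1040 ms at
# 785 nm; voxel size 20 um isotropic after downsampling.
"405":
  emission_filter: "525/50"
  exposure_ms: 104
  laser_power: 1
  voxel_size_um: [20, 20, 20]
"488":
  emission_filter: "535/30"
  exposure_ms: 104
  laser_power: 1
  voxel_size_um: [20, 20, 20]
"561":
  emission_filter: "620/20"
  exposure_ms: 104
  laser_power: 1
  voxel_size_um: [20, 20, 20]
"640":
  emission_filter: "680/30"
  exposure_ms: 104
  laser_power: 1
  voxel_size_um: [20, 20, 20]
"785":
  emission_filter: "845/55"
  exposure_ms: 1040
  laser_power: 1
  voxel_size_um: [20, 20, 20]
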