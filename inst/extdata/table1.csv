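animal_id,size_stratum,pre_volume_mm3,post_volume_mm3,printed_tvr,printed_category
mouse01,small,62.5,32.0,-48.8,PR
mouse02,small,40.0,18.0,-55.0,PR
mouse03,small,75.0,75.0,0.0,SD
mouse04,small,87.5,105.9,21.0,SD
mouse05,small,75.0,211.0,181.3,PD
mouse06,small,135.0,232.8,72.4,PD
mouse07,large,162.0,70.0,-56.3,PR
mouse08,large,386.0,60.8,-84.3,PR
mouse09,large,575.0,550.0,-4.3,SD
mouse10,large,169.0,171.5,1.5,SD
mouse11,large,245.0,225.0,-8.2,SD
mouse12,large,208.3,288.0,38.3,PD
mouse13,large,180.0,309.4,71.9,PD
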