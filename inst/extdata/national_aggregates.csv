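unit_id,region_id,year,enrolled,unassigned,gp_fte
NATIONAL,NATIONAL,2009,11293000,1800000,5650
NATIONAL,NATIONAL,2023,10500000,1700000,5395
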