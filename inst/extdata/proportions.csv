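taxon,part,part_length_mm,whole_length_mm
Thalassomedon,caudal_of_postcervical,1216,4299
Albertonectes,caudal_of_postcervical,1860,4180
Morenosaurus,caudal_of_postcervical,1632,3627
Nakonanectes,neck_of_postcranial,2083,5300
Albertonectes,neck_of_postcranial,7000,11200
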