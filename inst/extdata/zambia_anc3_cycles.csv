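source_kind,source_name,country,geo_path,geo_level_type,year_raw,season,indicator_id,n,estimate,sd,population
reference,DHS,Zambia,Zambia>Central,province,2013/14,unknown,anc_3plus_visits,789,89.2,,
reference,DHS,Zambia,Zambia>Copperbelt,province,2013/14,unknown,anc_3plus_visits,853,91.3,,
reference,DHS,Zambia,Zambia>Eastern,province,2013/14,unknown,anc_3plus_visits,1136,89.1,,
reference,DHS,Zambia,Zambia>Luapula,province,2013/14,unknown,anc_3plus_visits,988,88.2,,
reference,DHS,Zambia,Zambia>Lusaka,province,2013/14,unknown,anc_3plus_visits,904,88.5,,
reference,DHS,Zambia,Zambia>Muchinga,province,2013/14,unknown,anc_3plus_visits,850,86.7,,
reference,DHS,Zambia,Zambia>North Western,province,2013/14,unknown,anc_3plus_visits,927,86.1,,
reference,DHS,Zambia,Zambia>Northern,province,2013/14,unknown,anc_3plus_visits,981,85.4,,
reference,DHS,Zambia,Zambia>Southern,province,2013/14,unknown,anc_3plus_visits,1036,89.9,,
reference,DHS,Zambia,Zambia>Western,province,2013/14,unknown,anc_3plus_visits,793,85.2,,
reference,DHS,Zambia,Zambia,country,2013/14,unknown,anc_3plus_visits,9257,88.5,,
reference,DHS,Zambia,Zambia>Central,province,2018,unknown,anc_3plus_visits,746,89.0,,
reference,DHS,Zambia,Zambia>Copperbelt,province,2018,unknown,anc_3plus_visits,730,91.4,,
reference,DHS,Zambia,Zambia>Eastern,province,2018,unknown,anc_3plus_visits,875,93.6,,
reference,DHS,Zambia,Zambia>Luapula,province,2018,unknown,anc_3plus_visits,817,91.9,,
reference,DHS,Zambia,Zambia>Lusaka,province,2018,unknown,anc_3plus_visits,818,89.3,,
reference,DHS,Zambia,Zambia>Muchinga,province,2018,unknown,anc_3plus_visits,661,91.2,,
reference,DHS,Zambia,Zambia>North Western,province,2018,unknown,anc_3plus_visits,608,92.6,,
reference,DHS,Zambia,Zambia>Northern,province,2018,unknown,anc_3plus_visits,692,90.6,,
reference,DHS,Zambia,Zambia>Southern,province,2018,unknown,anc_3plus_visits,746,94.5,,
reference,DHS,Zambia,Zambia>Western,province,2018,unknown,anc_3plus_visits,612,90.4,,
reference,DHS,Zambia,Zambia,country,2018,unknown,anc_3plus_visits,7305,91.5,,
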