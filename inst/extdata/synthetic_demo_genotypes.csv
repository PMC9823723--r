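23,16,3,7,9,7
ssrcurate export,,siteB,siteA,siteC
accession_id,collection,assumed_name,pomological_status,determined_name,lab_batch,L01.1,L01.2,L02.1,L02.2,L03.1,L03.2,L04.1,L04.2,L05.1,L05.2,L06.1,L06.2,L07.1,L07.2,L08.1,L08.2,L09.1,L09.2,L10.1,L10.2,L11.1,L11.2,L12.1,L12.2,L13.1,L13.2,L14.1,L14.2,L15.1,L15.2,L16.1,L16.2
T0001,siteB,CV001,determined,CV001,lab1,224,240,164,170,170,170,202,212,115,116,304,310,160,160,290,306,275,276,144,146,100,138,126,134,156,180,208,208,130,130,146,150
T0002,siteA,CV001,determined,CV001,lab1,224,240,154,164,170,170,200,212,116,116,304,310,160,160,290,306,274,276,144,146,100,108,126,134,156,156,208,208,130,130,150,156
T0003,siteB,CV001,determined,CV001,lab1,224,240,164,170,170,174,202,212,116,116,304,310,160,162,290,306,274,276,144,146,100,108,126,134,0,0,208,208,130,130,146,150
T0004,siteB,CV002,determined,CV002,lab1,218,232,164,169,170,174,212,212,116,116,304,318,168,168,292,292,280,280,140,160,136,136,124,132,170,176,208,234,130,130,150,150
T0005,siteB,CV002,determined,CV002,lab1,232,234,164,170,170,174,212,212,116,116,304,318,168,168,292,292,280,280,140,160,136,136,124,132,170,176,208,234,130,130,150,150
T0006,siteA,CV002,with_reservation,CV002,lab1,234,240,164,172,170,174,212,212,116,116,304,318,162,168,292,292,280,280,140,160,136,136,124,132,170,176,208,233,130,130,150,150
T0007,siteA,CV003,determined,CV003,lab1,212,212,165,166,170,174,218,218,116,116,296,314,164,168,298,314,280,290,138,144,102,136,124,132,156,170,208,246,114,116,150,150
T0008,siteC,CV003,determined,CV003,lab1,212,212,164,166,170,174,218,218,116,116,296,314,164,168,298,314,280,290,138,144,102,136,124,132,156,170,208,246,116,130,150,150
T0009,siteB,CV004,determined,CV004,lab1,210,240,170,172,0,0,0,0,112,116,304,318,160,168,300,302,274,284,144,146,0,0,124,132,156,156,208,246,130,130,150,151
T0010,siteC,CV004,determined,CV004,lab1,230,240,170,172,170,174,212,222,112,116,304,318,160,168,300,302,274,280,0,0,134,136,124,132,156,156,208,246,130,130,150,150
T0011,siteA,CV005,determined,CV005,lab1,234,240,164,171,174,174,212,212,112,116,304,304,160,168,290,306,280,298,142,162,116,142,122,124,152,152,208,208,111,130,150,150
T0012,siteA,CV006,determined,CV006,lab1,210,232,170,172,170,176,204,226,116,116,296,304,156,160,291,296,280,298,140,160,102,112,116,122,156,156,206,214,116,124,150,150
T0013,siteA,CV006,determined,CV006,lab1,210,222,170,172,170,176,204,226,116,116,296,320,160,160,292,296,280,298,140,160,102,114,116,122,156,156,206,214,116,124,150,150
T0014,siteB,CV007,no_reference,,lab1,212,240,164,170,170,176,198,218,116,116,304,306,168,168,290,314,280,280,160,178,100,100,124,132,140,156,208,226,120,130,150,150
T0015,siteC,CV008,determined,CV008,lab1,212,212,164,182,170,174,202,218,0,0,304,310,150,174,290,300,274,294,144,146,128,138,116,122,156,164,208,208,112,130,150,150
T0016,siteC,CV008,determined,CV008,lab1,212,212,160,182,170,174,202,218,116,116,304,310,150,160,290,300,274,294,144,146,128,138,116,122,156,164,208,208,112,130,150,154
T0017,siteA,CV009,determined,CV009,lab1,212,233,170,172,174,176,212,218,112,116,310,318,168,168,290,302,280,312,166,178,102,134,122,124,156,156,208,208,130,130,0,0
T0018,siteA,CV010,determined,CV010,lab1,240,240,168,170,170,170,212,212,116,116,296,306,0,0,292,302,286,290,155,160,0,0,122,138,155,156,208,232,130,130,146,150
T0019,siteC,CV010,not_determined,,lab1,240,240,0,0,170,170,212,212,116,116,296,306,150,164,292,302,286,290,144,160,100,100,122,132,156,156,208,232,130,130,146,150
T0020,siteA,CV011,determined,CV011,lab1,212,234,166,170,170,174,212,218,112,116,296,304,164,168,290,298,280,298,138,142,102,142,120,122,152,170,208,246,116,120,150,150
T0021,siteC,CV011,determined,CV011,lab1,212,234,166,170,170,174,212,218,112,116,296,304,164,168,290,298,280,298,138,176,102,142,122,124,152,170,0,0,116,130,150,150
T0022,siteB,CV011,determined,CV011,lab1,212,234,166,170,0,0,212,218,111,116,296,304,164,168,290,298,280,298,138,142,102,142,122,124,152,170,208,246,116,130,150,150
T0023,siteC,CV012,determined,CV012,lab1,210,240,170,170,170,170,212,222,116,116,304,306,150,168,302,302,274,286,146,156,100,134,122,132,156,156,208,246,130,130,150,150
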