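station_id,barangay,municipality,lat,lon,elevation_m
BGW1,Tagwak,Boac,13.44552,121.87620,96
BGW2,Maligaya,Boac,13.47936,121.84087,10
BGW3,Puting Buhangin,Boac,13.45117,121.96087,282
BGW4,Balarin,Boac,13.41933,121.82200,17
BGW5,Bantay,Boac,13.43247,121.90953,208
BGW6,Hinapulan,Boac,13.41442,121.94785,242
BGW7,Boton,Boac,13.44292,121.86732,61
MGW1,Sumangga,Mogpog,13.47268,121.87412,68
MGW2,Nangka Dos (Site 1),Mogpog,13.47972,121.85047,24
MGW3,Nangka Dos (Site 2),Mogpog,13.47973,121.85053,24
MGW4,Janagdong,Mogpog,13.46952,121.85326,29
MGW5,Butansapa,Mogpog,13.48100,121.91803,145
MGW6,Putting Buhangin,Mogpog,13.45533,121.95198,265
BVGW1,Malbog (Site 1),Buenavista,13.25813,121.94488,77
BVGW2,Malbog (Site 2),Buenavista,13.26675,121.91648,103
BVGW3,Libas (Site 1),Buenavista,13.25553,121.93958,69
BVGW4,Libas (Site 2),Buenavista,13.26807,121.95612,70
BVGW5,Bagtingon,Buenavista,13.20521,121.99482,85
BVGW6,Sihi,Buenavista,13.25813,121.94488,371
GGW1,Banuyo,Gasan,13.27573,121.89303,5
GGW2,Masiga,Gasan,13.35505,121.82912,16
GGW3,Libtangin,Gasan,13.34647,121.83297,21
GGW4,Matandang Gasan,Gasan,13.32178,121.85268,46
GGW5,Dawis,Gasan,13.28638,121.88908,42
GGW6,Tiguion,Gasan,13.34365,121.86365,86
TGW1,Marlangga,Torrijos,13.32683,122.08442,56
TGW2,Poctoy (Site 1),Torrijos,13.32943,122.09528,37
TGW3,Dampulan,Torrijos,13.22590,122.04562,25
TGW4,Sibuyao,Torrijos,13.34091,122.01261,444
TGW5,Poctoy (Site 2),Torrijos,13.33164,122.01261,34
TGW6,Matuyatuya,Torrijos,13.37778,122.11611,15
SGW1,San Antonio,Santa Cruz,13.44612,121.98055,272
SGW2,Dolores (Site 1),Santa Cruz,13.49177,121.96383,185
SGW3,Dolores (Site 2),Santa Cruz,13.49183,121.96087,191
SGW4,Napo,Santa Cruz,13.43878,122.07607,65
SGW5,Matalaba,Santa Cruz,13.46595,122.05897,53
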