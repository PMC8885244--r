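橄	木
榄	木
油	水
含	口
有	月
不	一
饱	食
和	口
脂	月
肪	月
酸	酉
恩	心
诺	讠
沙	氵
星	日
属	尸
于	二
第	竹
三	一
代	亻
喹	口
酮	酉
类	米
是	日
合	口
成	戈
广	广
谱	讠
抗	扌
菌	艹
药	艹
物	牛
鱼	鱼
的	白
皮	皮
中	丨
检	木
出	凵
最	曰
大	大
残	歹
留	田
限	阝
量	里
肉	肉
食	食
纤	纟
维	纟
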